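# Shared fixtures: small, fast generators used across test files.

# Short OU (harmonic-well) trajectory: k = 4 kT/nm^2 at r0 = 2 nm, D = 0.1.
ou_traj <- function(n_steps = 2e6, seed = 1, dt = 0.005, stride = 2) {
  cfg <- sim_config(dt = dt, n_steps = n_steps, seed = seed,
                    domain = c(0.5, 3.5), save_stride = stride)
  simulate_diffusion_1d(potential_harmonic(2, 4), diffusion_constant(0.1),
                        cfg)
}

# Random detailed-balance birth-death generator on nb bins.
random_rate_matrix <- function(nb = 10, seed = 1) {
  set.seed(seed)
  grid <- structure(list(edges = seq(0, 1, length.out = nb + 1),
                         centers = seq(0.5 / nb, 1 - 0.5 / nb,
                                       length.out = nb),
                         h = 1 / nb, n_bins = as.integer(nb)),
                    class = "bin_grid")
  build_rate_matrix(diffusion_landscape(runif(nb, 0, 3),
                                        runif(nb - 1, 0.05, 0.5), grid))
}

# Small coupled (E, counts) ensemble set with pseudo-experimental targets.
small_ensembles <- function(n_proteins = 6, n_frames = 4000, eps_sb = 0.5,
                            seed = 3) {
  synthesize_saltbridge_ensemble(n_proteins, n_frames,
                                 truth = salt_bridge_params(eps_sb = eps_sb),
                                 seed = seed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
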