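#' Overdamped Rouse chain dynamics
#'
#' Simulates an ideal (Gaussian) chain of `n_beads` beads connected by
#' harmonic bonds with spring constant 3/b^2 kT/nm^2 (so the equilibrium
#' mean-square bond length is b^2 = `bond_scale`^2), each bead diffusing with
#' coefficient `bead_D`. Initial coordinates are drawn from the equilibrium
#' Gaussian-chain ensemble. At stationarity the mean-square end-to-end
#' distance is (n_beads - 1) b^2, and the end-to-end vector relaxes as the
#' odd-mode Rouse sum.
#'
#' @param n_beads Number of beads (>= 3; use [simulate_diffusion_1d()] for a
#'   dumbbell analogue).
#' @param bond_scale Root-mean-square bond length b (nm).
#' @param bead_D Per-bead diffusion coefficient (nm^2/ns).
#' @param config A [sim_config()]; its `domain` is ignored (the chain is
#'   unconfined).
#' @param save_coords If TRUE, also return the strided bead coordinates.
#' @return A list with `traj` (a [distance_trajectory()] of the end-to-end
#'   distance) and, if requested, `coords` (matrix n_saved x 3*n_beads,
#'   bead-major xyz triples).
#' @export
simulate_rouse_chain <- function(n_beads, bond_scale, bead_D, config,
                                 save_coords = FALSE) {
  stop_if(n_beads < 3, "n_beads must be at least 3")
  stopifnot(inherits(config, "sim_config"))
  res <- with_seed(config$seed, {
    bonds <- matrix(rnorm(3 * (n_beads - 1), sd = bond_scale / sqrt(3)),
                    ncol = 3)
    coords0 <- rbind(0, apply(bonds, 2, cumsum))
    rouse_core(coords0, config$n_steps, config$dt, bead_D, bond_scale,
               config$save_stride, save_coords)
  })
  traj <- distance_trajectory(res$ree, config$dt * config$save_stride,
                              label = sprintf("rouse_n%d", n_beads),
                              provenance = list(seed = config$seed,
                                                n_beads = n_beads,
                                                bond_scale = bond_scale,
                                                bead_D = bead_D))
  if (save_coords) list(traj = traj, coords = res$coords) else list(traj = traj)
}

#' Analytic Rouse end-to-end vector autocorrelation
#'
#' Closed-form normal-mode expression for the normalized autocorrelation of
#' the end-to-end vector of a discrete Rouse chain with N beads, bond length
#' b and bead diffusivity D: a sum over odd modes p with amplitudes
#' cot^2(p pi / 2N)-weighted and rates 12 D sin^2(p pi / 2N) / b^2. Used as an
#' independent oracle for [simulate_rouse_chain()].
#'
#' @param t Times (ns).
#' @param n_beads,bond_scale,bead_D As in [simulate_rouse_chain()].
#' @return Normalized autocorrelation values at `t`.
#' @export
rouse_ee_acf <- function(t, n_beads, bond_scale, bead_D) {
  N <- n_beads
  p <- seq(1, N - 1, by = 2) # odd modes carry the end-to-end vector
  s <- sin(p * pi / (2 * N))
  amp <- (cos(p * pi / (2 * N)) / s)^2
  rate <- 12 * bead_D * s^2 / bond_scale^2
  sapply(t, function(tt) sum(amp * exp(-rate * tt))) / sum(amp)
}
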