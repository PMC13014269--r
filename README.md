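# dynabuffer

Analysis of end-to-end distance dynamics in intrinsically disordered
proteins (IDPs), for researchers combining single-molecule FRET /
nanosecond fluorescence correlation spectroscopy (nsFCS) with molecular
simulation.

Disordered proteins of the same length can differ widely in compaction, yet
their chain reconfiguration times τ_r — the correlation time of the
end-to-end (dye-to-dye) distance r — often cluster tightly. The package
implements the full computational chain needed to quantify and explain this
*dynamical buffering*: for near-harmonic distance dynamics with constant
diffusion coefficient,

    τ_r = Var[r] / D,

so a narrowing distance distribution (smaller Var[r]) can compensate a
reduced intrachain diffusivity D, leaving τ_r nearly sequence independent.

## What the package computes

- **FRET observables from trajectories** — instantaneous orientational
  factor κ² = (d̂_D·d̂_A − 3(d̂_D·r̂)(d̂_A·r̂))², transfer rate
  k_F = k_D (κ²/(2/3)) (R₀/r)⁶, donor excited-state survival
  p_D\*(t) = ⟨exp(−∫[k_D + k_F] dt′)⟩ over excitation origins, mean
  efficiency ⟨E⟩ = 1 − k_D ∫ p_D\* dt, the dye-less mapping
  r = d((N+9)/N)^ν, and weighted Var[E].
- **SAW-ν polymer model** — end-to-end distance densities
  P(r) ∝ (r/ℓ)^(2+g) exp(−α(r/ℓ)^δ), inference of the scaling exponent ν
  from a measured ⟨E⟩, observable correlation times
  τ_X = ∫P⁻¹[∫δX P]² dr / (D ∫δX² P dr), and the conversion factor
  ϑ = τ_r/τ_E that turns measured efficiency correlation times into
  reconfiguration times.
- **1D diffusion landscapes** — discretization of distance trajectories
  into 30 equal bins, lagged transition counts, Bicout–Szabo
  nearest-neighbour rate matrices K with detailed balance, transition-count
  likelihood ln L = ΣN_ji ln(exp[ΔtK])_ji, Metropolis inference of per-bin
  free energies and (position-dependent) diffusivities, and spectral
  correlation functions/times.
- **Ensemble reweighting** — salt-bridge counting (possible pairs,
  hysteretic 0.38/0.8 nm contact states), Boltzmann reweighting
  w_i ∝ exp(−Σ N_AB ε_AB), the χ² scan for a uniform correction ε_sb,
  regularized adaptive gradient descent for the four type-specific
  corrections (Glu–Lys, Glu–Arg, Asp–Lys, Asp–Arg), and Bayesian
  (maximum-entropy) reweighting to match ⟨E⟩ and Var[E].
- **nsFCS analysis** — photon/intensity correlators, global fits of the
  nsFCS model (antibunching + chain dynamics + triplet) and of the
  multiplicative efficiency-correlation model, quadrature uncertainty
  combination, viscosity-series intercepts (internal friction).
- **Cross-protein statistics** — Monte-Carlo correlation coefficients
  ρ_MC, Lin's concordance, sequence descriptors (NCPR, FCR,
  hydrophobicity, possible salt bridges, κ patterning, SCD) and the
  fixed-D / fixed-Var / full buffering decomposition.
- **Synthetic data with known ground truth** for every stage: Brownian
  dynamics on arbitrary 1D landscapes (Itô drift-corrected for
  position-dependent D), Rouse chains, isotropic dye dipoles, closed-form
  correlation curves, photon streams, and salt-bridge-perturbed ensembles.

## Worked example

Simulate distance dynamics in a harmonic well (stiffness 4 kT/nm², D =
0.1 nm²/ns, so τ_r = Var[r]/D = 2.5 ns), infer the landscape back from the
trajectory alone, and check the relaxation time:

```r
library(dynabuffer)

cfg  <- sim_config(dt = 0.005, n_steps = 2e7, seed = 1,
                   domain = c(0.5, 3.5), save_stride = 20)
traj <- simulate_diffusion_1d(potential_harmonic(r0 = 2, k = 4),
                              diffusion_constant(0.1), cfg)
traj
#> <distance_trajectory> bd_harmonic: 1000000 frames, dt = 0.1 ns, range [0.500, 3.500] nm

disc   <- discretize(traj, n_bins = 30)
counts <- count_transitions(disc$indices, traj$dt_out, lags = c(0.5, 1, 2))
fit    <- fit_landscape(counts, disc$grid, mode = "constant_D",
                        n_steps = 6000, seed = 2)
fit$ml
#> <diffusion_landscape> 30 bins over [0.500, 3.500] nm; D = 0.103 nm^2/ns; F range 4.21 kT

correlation_time(build_rate_matrix(fit$ml))
#> [1] 2.40   # ns, vs Var[r]/D = 2.38 ns from the trajectory itself
```

The recovered diffusivity (0.103 nm²/ns) and the harmonic free-energy
profile match the generating model, and the spectral correlation time of
the fitted rate matrix agrees with Var[r]/D.

Converting a measured efficiency correlation time into a reconfiguration
time goes through the SAW-ν model:

```r
rec <- reconfiguration_time(tau_E_nsfcs = 21.5, tau_E_ecorr = 23.8, E = 0.55)
rec
#> <reconfig_result> E = 0.550 -> nu = 0.583, theta = 1.058; tau_r = 23.97 +/- 3.39 ns
```

Here ν = 0.583 is inferred from ⟨E⟩ = 0.55 (R₀ = 6 nm, 56 + 9 effective
segments), ϑ = 1.058 converts τ_E to τ_r, and the two analysis routes are
averaged with their uncertainties combined in quadrature.

## Layout

- `R/`, `src/` — implementation (R plus two small Rcpp simulation cores)
- `tests/testthat/` — unit, property and end-to-end recovery tests
- `vignettes/dynamical-buffering.Rmd` — methods notes: models, parameter
  choices, numerics, limitations
- `scripts/acceptance.R` — see above
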