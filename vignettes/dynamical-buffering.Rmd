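---
title: "Methods: reconfiguration dynamics and dynamical buffering of disordered proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconfiguration dynamics and dynamical buffering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynabuffer)
```

This vignette documents the models implemented in `dynabuffer`, the
parameter choices that matter, the numerical decisions, and what the
synthetic-data tests do and do not demonstrate about real data.

## The scientific setting

Single-molecule FRET on a dye-labeled disordered chain reports on the
interdye distance r through the steeply distance-dependent transfer
efficiency, and nanosecond FCS resolves the relaxation of E-fluctuations,
giving an efficiency correlation time τ_E. The chain *reconfiguration
time* τ_r is the correlation time of r itself. All-atom simulations give
direct access to r(t); experiments reach τ_r from τ_E through a polymer
model. For diffusive motion in a one-dimensional harmonic potential with
constant diffusion coefficient, τ_r = Var[r]/D. Because compact chains
have both smaller Var[r] and smaller intrachain diffusivity, the two
trends can cancel — *dynamical buffering* — which is the central effect
the pipeline quantifies.

## FRET observables (module `fret`)

The explicit-dye route integrates the donor excited-state survival
p\*(t) = ⟨exp(−∫ [k_D + k_F(t′)] dt′)⟩ over all excitation origins with a
full window ahead, with k_F = k_D (κ²/(2/3)) (R₀/r)⁶ and κ² computed
per frame from the dipole geometry; ⟨E⟩ = 1 − k_D ∫₀^t_max p\*(t) dt.
Defaults: R₀ = 6.0 nm, t_max = 20 ns (long enough for the survival to
decay in practice; a warning fires when p\*(t_max) > 10⁻³), frame spacing
0.02 ns, trapezoidal integration (the frame spacing is far below 1/k_D, so
the quadrature error is ~10⁻⁴ relative, checked in the tests).

Dye quenching: frames in which any donor–acceptor heavy-atom pair is
closer than 0.4 nm (van der Waals contact) are treated as nonemissive.
Two conventions are implemented because the physical bookkeeping is
genuinely ambiguous: `"absorb"` (default) terminates the survival at the
first quenched frame after the origin, which counts the origin as a
transfer-like event — the rationale being that removing donor photons is
scored by ratiometric detection as acceptor signal; `"exclude"` drops such
origins from the average entirely. The choice is an explicit argument and
is recorded by callers.

The dye-less route maps Cα–Cα distances through r = d((N+9)/N)^ν with
ν = 0.6, i.e. nine effective residues account for dyes and linkers, and
uses κ² = 2/3. The ν-sensitivity of this route is exposed as a
computation rather than a constant: over distances mapping to
E ∈ [0.4, 0.9] at N = 56, moving ν from 0.6 to 0.7 changes E by at most
0.025 (a property test), with typical changes around ±0.01.

## SAW-ν distance distributions (module `sawnu`)

The one-parameter family
P(r) = A (r/ℓ)^(2+g) exp(−α (r/ℓ)^δ), g = (γ−1)/ν, δ = 1/(1−ν),
interpolates between compact and self-avoiding statistics; γ = 1.1615 (the
universal SAW exponent) is exposed as a parameter, and γ = 1 with ν = 1/2
recovers the Gaussian chain exactly (used as a closed-form oracle in the
tests). A and α follow in closed form from normalization and from the
calibration ⟨r²⟩ = ℓ². The length scale defaults to ℓ = b·n^ν with
b = 0.55 nm and n = N + 9 effective segments, consistent with the dye-less
mapping; b and n are arguments because the calibration convention is not
universal.

ν is inferred from a measured ⟨E⟩ by bracketed root finding on
ν ∈ [0.34, 0.72] (the forward map ν → ⟨E⟩ is strictly decreasing;
out-of-range observations report the achievable boundary instead of
silently clamping).

For any observable X(r), the correlation time of overdamped diffusion on
the potential of mean force −ln P(r) is
τ_X = ∫ P(r)⁻¹ [∫₀^r δX P dρ]² dr / (D ∫ δX² P dr).
With X = r on a Gaussian this reduces to Var[r]/D exactly (quadrature
tolerance 10⁻⁶ in the tests), which certifies the mutual consistency of
the harmonic-well expression and the general integral as used here. The
conversion factor ϑ = τ_r/τ_E is the ratio of the X = r and X = E
correlation times; D cancels, so no experimental diffusivity is needed.
Radial integrals are truncated where P < 10⁻¹² × peak — the P⁻¹ factor is
benign there because the bracketed cumulative term vanishes faster — and
quadrature grids (6001 points) are fine enough that halving the step
changes results by < 10⁻⁶ (tested).

## Discretized diffusion model (module `diffusion1d`)

Distance trajectories are discretized into 30 equal bins spanning the
sampled range (the maximum sample closes the last bin). Transition counts
N_ji(Δt) use every frame with a full lag ahead as an origin; lags default
to 5, 10 and 20 ns for trajectories on the experimental time scale and are
scaled to ~τ/5 … 2τ for synthetic data (the tests use 0.5/1/2 ns where
τ = 2.5 ns). Lags are converted to frames by rounding; a mismatch beyond
1% errors out.

The landscape maps to a birth–death generator with hopping rates
K_i±1,i = (D_interface/h²) exp(−(F_neighbour − F_i)/2), which satisfies
detailed balance with p_eq ∝ exp(−F) exactly. The likelihood is
ln L = Σ_lags Σ N_ji ln (exp[ΔtK])_ji with propagator entries floored at
10⁻³⁰⁰. Parameters (per-bin F, per-interface ln D — or a single ln D in
the constant-D variant) are sampled by Metropolis with flat priors.
Numerical decisions:

- **Eigenvector normalization.** The spectral weights of the distance
  autocorrelation are computed through the symmetrized matrix
  S = P_eq^(−1/2) K P_eq^(1/2) with orthonormal eigenvectors φ_n, giving
  w_n = (Σ_i r_i √p_eq,i φ_n,i)². With this choice C(t) equals the exact
  normalized autocorrelation of the stationary Markov chain — enforced in
  the tests against matrix-exponential propagation to 10⁻⁸ — and
  τ = Σ w_n |λ_n|⁻¹ / Σ w_n equals ∫C dt. Raw right-eigenvector
  projections depend on an arbitrary scaling; this convention removes the
  ambiguity.
- **Gauge and empty bins.** F of the most occupied bin is fixed at 0;
  empty bins are capped at F = 20 kT to keep the generator irreducible.
- **Proposals.** Gaussian steps, σ = 0.2 kT on F and 0.1 on ln D, one
  random coordinate per step, with 20% of steps shifting all ln D jointly
  (decorrelates the global time scale). The chain is initialized from the
  occupancy free energies and a short-lag mean-square-displacement
  diffusivity, so run lengths of 6,000 (constant D) to 30,000
  (position-dependent) steps suffice for the recovery tests; chain length
  and proposal widths are exposed because no single setting fits all data.
  Acceptance below 1% warns. Both maximum-likelihood and posterior-mean
  (second half of chain) parameters are returned, since which of the two a
  given analysis should report is a user decision.

Recovery, demonstrated in the tests at 10⁶ frames: constant D within 10%
(typically ~3%), harmonic F with R² > 0.98, monotone position-dependent
D(r) profiles with rank correlation > 0.8, and pipeline correlation times
within 10% of the trajectory's own autocorrelation time.

## Salt-bridge reweighting (module `reweight`)

Frames are reweighted by w_i ∝ w⁰_i exp(−Σ_AB N_AB(i) ε_AB) (max-shifted
exponent, renormalized). The uniform correction is found by a χ² scan; the
four type-specific corrections by gradient descent with the analytical
gradient ∂χ²/∂ε_AB = (2/σ²)(⟨E⟩_rw − E_expt)(⟨E⟩_rw⟨n_AB⟩_rw −
⟨E n_AB⟩_rw) summed over proteins, an adaptive step (×1.2 on decrease,
×0.5 with rejection on increase) and the regularizer ½γ(Σε)², γ = 1.0.

**Why the χ² is σ-weighted by default.** With raw E-scale residuals
(~10⁻²), a γ = 1.0 penalty on (Σε)² would dominate the objective by
orders of magnitude for corrections of a few kT and force Σε toward 0, so
"γ penalizes large energies" would be the whole story rather than a mild
regularization. Dividing by the experimental uncertainty σ = 0.03 of each
mean efficiency puts the data term on the scale on which γ = 1.0 is the
mild penalty it is meant to be. `chi2_and_grad(..., sigma = NULL)` gives
the literal unweighted form for comparison.

Per-frame salt-bridge states can be counted with the hysteretic contact
automaton (formed below 0.38 nm, broken above 0.8 nm) or a single cutoff;
both are exposed because the appropriate definition depends on the
sampling interval of the trajectory at hand.

Bayesian reweighting minimizes θ·KL(w‖w⁰) + ½χ²(w) with χ² built from
⟨E⟩_w (σ = 0.03) and Var_w[E] (σ = 0.02). The stationary weights have the
two-parameter exponential-family form w_i ∝ w⁰_i exp(−(λ₁E_i + λ₂E_i²)/θ),
so the problem is solved in the dual space (BFGS plus a Nelder–Mead
polish) — verified in the tests against direct minimization over the full
simplex at small n. θ defaults to 10 and must be reported with any result;
no automatic selection is attempted. Targets outside the convex hull of
the frame observables are flagged as infeasible.

## nsFCS and efficiency correlation (module `fcs`)

Intensity correlations G_ab(τ) = ⟨δI_a δI_b⟩/(⟨I_a⟩⟨I_b⟩) are estimated
from photon streams binned at the lag spacing (default 1 ns over
0–100 ns); autocorrelations subtract the zero-lag shot-noise spike. The
nsFCS model is the additive form
G(τ) = (1/N)(1 + c_ab e^(−τ/τ_ab) + c_cd e^(−τ/τ_cd) + c_t e^(−τ/τ_t)),
fitted jointly to dd/aa/da with τ_cd global and all amplitudes free in
sign; the efficiency correlation uses the multiplicative
(1 − c_ab e)(1 + c_cd e)(1 + c_t e) form. Fits use variable projection
(amplitudes are linear given the time scales) with a coarse time-scale
grid for starting values, refined by Levenberg–Marquardt; noiseless
round trips are exact to 10⁻⁶ relative. Identifiability of τ_cd is checked
by refitting without the chain-dynamics component: if the fit is equally
good, the result is flagged. A caveat the tests make explicit: with a
0–100 ns window and a triplet time of several hundred ns the model is
ill-conditioned (the triplet term is nearly constant over the window) and
parameters trade off; exact round trips are demonstrated on windows long
enough to constrain all components, and window-dependence is precisely
what the systematic-uncertainty protocol (refitting over 100–1000 ns
windows; two-step shared-triplet fits for the efficiency correlation)
quantifies.

τ_r = ϑ·τ_E per route, arithmetic mean across routes; statistical
uncertainties default to 10% of each measured time (the replicate-based
figure for this kind of measurement) when no replicates are supplied,
systematic components come from the window/shared-parameter protocols, and
the four components combine in quadrature.

## Cross-protein statistics (module `report`)

ρ_MC resamples each point from Normal(mean, error) 100 times and reports
the mean ± sd of the per-set Pearson correlations (zero errors reproduce
plain Pearson exactly). Lin's concordance uses population moments.
Sequence descriptors: NCPR, FCR (D/E = −1, K/R = +1, histidine neutral,
termini uncharged), mean Kyte–Doolittle hydropathy rescaled to [0, 1]
(the scale is configurable since conventions differ), possible salt
bridges (opposite charges ≥ 3 residues apart), SCD = (1/N)Σ q_i q_j
√(j−i), and κ charge patterning over blobs of 5 and 6 averaged, normalized
by the maximal-asymmetry rearrangement of the same composition (fully
segregated arrangement plus a deterministic shuffle search). The buffering
decomposition recomputes τ = Var[r]/D with (i) D fixed to the
cross-protein mean, (ii) Var[r] fixed to the mean, and (iii) both varying,
and correlates each set with ⟨E⟩; degenerate (zero-variance) cases are
flagged, never returned as NaN.

## Synthetic data: what it emulates and what it does not

The Brownian-dynamics generator integrates the Itô equation
dr = [−D(r)F′(r) + D′(r)]dt + √(2D(r)dt)·ξ; the spurious-drift term
D′(r) is required for the stationary law to remain Boltzmann when D
depends on position — exactly the assumption of the diffusion-model
inference, and the property the Boltzmann-consistency tests certify.
Reflecting boundaries fold the coordinate (stationary-law error O(dt)).
The default guard warns when max(D)·dt > 10⁻³·width². The Rouse generator
propagates an overdamped harmonic-bond chain whose end-to-end vector must
relax as the analytic odd-mode sum — an independent normal-mode oracle.

The salt-bridge ensemble generator couples per-frame counts and E through
a latent compactness variable (more bridges → more compact → higher E)
and defines pseudo-experimental targets as reweighted means *on the same
frames*, so the data term vanishes exactly at the generating parameters
and recovery is well-posed. The default panel of 16 proteins of equal
length crosses four compaction levels with four charge compositions, each
salt-bridge type dominating in a quarter of the panel — mirroring the
sequence diversity of a real IDR panel and making the four energy
components separately identifiable. Mean efficiencies span ~0.3–0.9 and
per-frame total counts are of order a few, as in all-atom ensembles of
~60-residue disordered regions. A known limitation, visible in the
recovery tests: a strongly positive correction (the Glu–Arg component at
3.75 kT) suppresses the frames carrying its own signal, so its recovered
value is biased low while the weakly perturbed components (notably
Glu–Lys) are recovered within ±0.15 kT; this is an identifiability
property of the reweighting method itself, not of the implementation.

What passing these tests shows: the estimators are consistent, their
oracles agree, and ground-truth parameters are recovered at realistic
sampling depth. What they cannot show: robustness to force-field error,
non-Markovian distance dynamics, dye photophysics beyond quenching-by-
contact and triplet blinking, or detector artifacts — none of which the
generators emulate.

## Problem sizes

The test suite and acceptance script run Brownian-dynamics trajectories of
10⁶ saved frames (2–4 × 10⁷ integration steps), 16 ensembles of 10⁵
frames, Metropolis chains of 6,000–30,000 steps, and correlation fits on
a few hundred lag points — sizes chosen so every stage has comfortable
statistical margin while the whole pipeline remains a desk-scale
computation.
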