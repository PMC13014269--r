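#' Simulation configuration
#'
#' @param dt Integration time step (ns).
#' @param n_steps Number of integration steps.
#' @param seed Integer seed (NULL = use current RNG stream).
#' @param domain Two-element vector `c(r_min, r_max)` (nm); reflecting
#'   boundaries.
#' @param save_stride Save every `save_stride`-th step, so the output sampling
#'   interval is `dt * save_stride`.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt, n_steps, seed = NULL, domain, save_stride = 1L) {
  stop_if(dt <= 0, "dt must be positive")
  stop_if(n_steps < 1, "n_steps must be at least 1")
  stop_if(length(domain) != 2 || domain[1] >= domain[2],
          "domain must be c(r_min, r_max) with r_min < r_max")
  stop_if(save_stride < 1, "save_stride must be at least 1")
  structure(list(dt = dt, n_steps = as.integer(n_steps), seed = seed,
                 domain = domain, save_stride = as.integer(save_stride)),
            class = "sim_config")
}

#' Distance trajectory container
#'
#' A uniformly sampled scalar distance time series: the universal dynamic
#' object of the pipeline (interdye or end-to-end distance).
#'
#' @param values Distances (nm), uniformly sampled.
#' @param dt_out Sampling interval (ns).
#' @param label Free-text label.
#' @param provenance Optional list recording how the series was generated
#'   (seed, generator parameters).
#' @return An object of class `"distance_trajectory"`.
#' @export
distance_trajectory <- function(values, dt_out, label = "",
                                provenance = list()) {
  stop_if(dt_out <= 0, "dt_out must be positive")
  structure(list(values = as.numeric(values), dt_out = dt_out, label = label,
                 provenance = provenance),
            class = "distance_trajectory")
}

#' @export
print.distance_trajectory <- function(x, ...) {
  cat(sprintf(
    "<distance_trajectory> %s: %d frames, dt = %g ns, range [%.3f, %.3f] nm\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$values), x$dt_out, min(x$values), max(x$values)))
  invisible(x)
}

#' Brownian dynamics on a 1D free-energy landscape
#'
#' Integrates overdamped diffusion dr = \[-D(r) F'(r) + D'(r)\] dt +
#' sqrt(2 D(r) dt) xi with the Ito spurious-drift term D'(r), so the
#' stationary distribution is Boltzmann, exp(-F(r)), even for
#' position-dependent diffusivity. Boundaries are reflecting (coordinate
#' folding). F is in kT, so no temperature parameter appears.
#'
#' @param potential A `"potential_spec"` (see [potential_harmonic()]).
#' @param diffusion A `"diffusion_spec"` (see [diffusion_constant()]).
#' @param config A [sim_config()]. A warning is issued when
#'   `max(D) * dt > 1e-3 * width^2` (step too coarse for the domain).
#' @param r_start Starting position (nm); default mid-domain.
#' @param n_grid Resolution of the internal drift/noise lookup tables.
#' @return A [distance_trajectory()] of the saved positions.
#' @examples
#' cfg <- sim_config(dt = 0.01, n_steps = 2e4, seed = 1, domain = c(0.5, 3.5),
#'                   save_stride = 10)
#' tr <- simulate_diffusion_1d(potential_harmonic(2, 4),
#'                             diffusion_constant(0.1), cfg)
#' @export
simulate_diffusion_1d <- function(potential, diffusion, config,
                                  r_start = NULL, n_grid = 2048L) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(diffusion, "diffusion_spec"),
            inherits(config, "sim_config"))
  lo <- config$domain[1]; hi <- config$domain[2]
  width <- hi - lo
  grid <- seq(lo, hi, length.out = n_grid)
  D <- diffusion_at(diffusion, grid)
  stop_if(any(D <= 0), "D(r) must be positive on the whole domain")
  if (max(D) * config$dt > 1e-3 * width^2) {
    warning("time step too coarse: max(D)*dt exceeds 1e-3 * domain width^2")
  }
  dFdr <- pot_dFdr(potential, grid)
  h <- grid[2] - grid[1]
  dDdr <- c(D[2] - D[1], (D[-(1:2)] - D[-((n_grid - 1):n_grid)]) / 2,
            D[n_grid] - D[n_grid - 1]) / c(h, rep(h, n_grid - 2), h)
  drift <- -D * dFdr + dDdr
  noise <- sqrt(2 * D * config$dt)
  if (is.null(r_start)) r_start <- (lo + hi) / 2
  stop_if(r_start < lo || r_start > hi, "r_start outside domain")
  vals <- with_seed(config$seed,
    bd_core(r_start, config$n_steps, config$dt, lo, hi, config$save_stride,
            drift, noise, lo, h))
  distance_trajectory(vals, config$dt * config$save_stride,
                      label = paste0("bd_", potential$form),
                      provenance = list(seed = config$seed, dt = config$dt,
                                        n_steps = config$n_steps,
                                        potential = potential$form,
                                        diffusion = diffusion$form))
}
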