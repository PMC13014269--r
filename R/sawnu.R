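#' SAW-nu end-to-end distance distribution model
#'
#' One-parameter family of polymer end-to-end distance distributions
#' interpolating between compact-globule and self-avoiding-walk statistics
#' through the length scaling exponent nu:
#' P(r) = A (r/l)^(2+g) exp(-alpha (r/l)^delta), with g = (gamma - 1)/nu,
#' delta = 1/(1 - nu), and A, alpha fixed in closed form by normalization and
#' by the calibration <r^2> = l^2. The length scale l defaults to
#' b n^nu with segment length b and n chain segments (for dye-labeled
#' constructs, n = N + 9 effective segments, consistent with the dye/linker
#' correction of [dyeless_distance()]).
#'
#' @param nu Scaling exponent, in (1/3, 1) (practically \[0.34, 0.72\]).
#' @param n_segments Number of chain segments (default 65 = 56 + 9).
#' @param length_scale Root-mean-square end-to-end distance l (nm);
#'   default `b * n_segments^nu`.
#' @param b Segment length prefactor (nm, default 0.55).
#' @param gamma Universal self-avoiding-walk exponent (default 1.1615);
#'   setting gamma = 1 with nu = 1/2 recovers the Gaussian-chain
#'   distribution.
#' @return An object of class `"saw_nu_model"`.
#' @examples
#' m <- saw_nu_model(0.55, n_segments = 65)
#' saw_moments(m)
#' @export
saw_nu_model <- function(nu, n_segments = 65, length_scale = NULL, b = 0.55,
                         gamma = 1.1615) {
  stop_if(nu <= 1 / 3 || nu >= 1, "nu must lie strictly between 1/3 and 1")
  if (is.null(length_scale)) length_scale <- b * n_segments^nu
  stop_if(length_scale <= 0, "length_scale must be positive")
  g <- (gamma - 1) / nu
  delta <- 1 / (1 - nu)
  alpha <- (gamma((5 + g) / delta) / gamma((3 + g) / delta))^(delta / 2)
  A <- delta * alpha^((3 + g) / delta) / gamma((3 + g) / delta)
  structure(list(nu = nu, n_segments = n_segments,
                 length_scale = length_scale, b = b, gamma = gamma,
                 g = g, delta = delta, alpha = alpha, A = A),
            class = "saw_nu_model")
}

#' @export
print.saw_nu_model <- function(x, ...) {
  cat(sprintf(
    "<saw_nu_model> nu = %.4f, n = %d segments, rms r = %.3f nm (gamma = %.4f)\n",
    x$nu, x$n_segments, x$length_scale, x$gamma))
  invisible(x)
}

#' SAW-nu probability density
#'
#' @param model A [saw_nu_model()].
#' @param r Distances (nm), >= 0.
#' @return Density values (1/nm); P(0) = 0.
#' @export
saw_nu_pdf <- function(model, r) {
  stop_if(any(r < 0), "r must be non-negative")
  x <- r / model$length_scale
  model$A * x^(2 + model$g) * exp(-model$alpha * x^model$delta) /
    model$length_scale
}

# Radial quadrature grid covering the support of the model down to
# P < 1e-12 * peak (tails beyond contribute nothing; the inverse-density
# factor of the correlation-time integrand is benign there because the
# cumulative term vanishes faster).
saw_grid <- function(model, n = 6001) {
  xmax <- (40 / model$alpha)^(1 / model$delta) # exp(-40) ~ 4e-18
  r <- seq(0, xmax * model$length_scale, length.out = n)
  p <- saw_nu_pdf(model, r)
  keep <- p >= 1e-12 * max(p)
  keep[1] <- TRUE
  list(r = r[keep], p = p[keep])
}

#' Moments of the SAW-nu distance distribution
#'
#' @param model A [saw_nu_model()].
#' @return List with `mean_r`, `var_r` (nm, nm^2) and `mean_r2`; by
#'   construction `mean_r2` equals `length_scale^2`.
#' @export
saw_moments <- function(model) {
  gr <- saw_grid(model)
  z <- trapz(gr$r, gr$p)
  m1 <- trapz(gr$r, gr$r * gr$p) / z
  m2 <- trapz(gr$r, gr$r^2 * gr$p) / z
  list(mean_r = m1, var_r = m2 - m1^2, mean_r2 = m2)
}

# Mean transfer efficiency of a SAW-nu model at Foerster radius R0.
saw_mean_efficiency <- function(model, R0 = 6.0) {
  gr <- saw_grid(model)
  E <- efficiency_of_distance(pmax(gr$r, 1e-9), R0)
  trapz(gr$r, E * gr$p) / trapz(gr$r, gr$p)
}

#' Infer the scaling exponent from a mean FRET efficiency
#'
#' Finds the unique nu for which the SAW-nu ensemble-averaged transfer
#' efficiency matches the observation, by bracketed root finding on
#' \[0.34, 0.72\]. The forward map nu -> <E> is strictly decreasing (larger
#' nu expands the chain and lowers E).
#'
#' @param E_obs Observed mean transfer efficiency, in (0, 1).
#' @param R0 Foerster radius (nm).
#' @param n_segments,b,gamma Passed to [saw_nu_model()].
#' @return The inferred nu.
#' @export
infer_nu <- function(E_obs, R0 = 6.0, n_segments = 65, b = 0.55,
                     gamma = 1.1615) {
  stop_if(E_obs <= 0 || E_obs >= 1, "E_obs must lie strictly in (0, 1)")
  f <- function(nu) {
    saw_mean_efficiency(saw_nu_model(nu, n_segments, b = b, gamma = gamma),
                        R0) - E_obs
  }
  at_lo <- f(0.34); at_hi <- f(0.72)
  if (at_lo < 0) {
    stop(sprintf("E_obs = %.3f above the achievable range (max %.3f at nu = 0.34)",
                 E_obs, at_lo + E_obs), call. = FALSE)
  }
  if (at_hi > 0) {
    stop(sprintf("E_obs = %.3f below the achievable range (min %.3f at nu = 0.72)",
                 E_obs, at_hi + E_obs), call. = FALSE)
  }
  uniroot(f, c(0.34, 0.72), tol = 1e-8)$root
}

#' Correlation time of a distance-dependent observable
#'
#' For overdamped diffusion with constant coefficient D in the potential of
#' mean force -ln P(r), the correlation time of any observable X(r) is
#' tau_X = integral P(r)^-1 \[integral_0^r dX(rho) P(rho) drho\]^2 dr /
#' (D integral dX(r)^2 P(r) dr) with dX = X - <X>. `correlation_time_1d` is
#' the generic quadrature on a tabulated density; `tau_observable` applies
#' it to a SAW-nu model with X the distance itself or the transfer
#' efficiency.
#'
#' @param r Coordinate grid (increasing).
#' @param p Density values on `r` (need not be normalized).
#' @param x Observable values on `r`.
#' @param D Diffusion coefficient (nm^2/ns), > 0.
#' @return Correlation time (ns).
#' @export
correlation_time_1d <- function(r, p, x, D) {
  stop_if(D <= 0, "D must be positive")
  z <- trapz(r, p)
  p <- p / z
  xbar <- trapz(r, x * p)
  dx <- x - xbar
  denom <- trapz(r, dx^2 * p)
  stop_if(denom <= 0, "observable is constant over the distribution")
  inner <- cumtrapz(r, dx * p)
  ok <- p > 1e-15 * max(p)
  num <- trapz(r[ok], inner[ok]^2 / p[ok])
  num / (D * denom)
}

#' @rdname correlation_time_1d
#' @param model A [saw_nu_model()].
#' @param X `"distance"` or `"efficiency"`.
#' @param R0 Foerster radius (nm), used when `X = "efficiency"`.
#' @export
tau_observable <- function(model, X = c("distance", "efficiency"), D,
                           R0 = 6.0) {
  X <- match.arg(X)
  gr <- saw_grid(model)
  xv <- if (X == "distance") gr$r
        else efficiency_of_distance(pmax(gr$r, 1e-9), R0)
  correlation_time_1d(gr$r, gr$p, xv, D)
}

#' Reconfiguration-to-efficiency correlation-time conversion factor
#'
#' theta = tau_r / tau_E, the ratio of the distance and transfer-efficiency
#' correlation times of diffusive dynamics over the SAW-nu distance
#' distribution. The diffusion coefficient cancels in the ratio, so no
#' experimental D estimate is needed.
#'
#' @param model A [saw_nu_model()].
#' @param R0 Foerster radius (nm).
#' @return Dimensionless conversion factor (> 0).
#' @export
conversion_factor <- function(model, R0 = 6.0) {
  tau_observable(model, "distance", D = 1) /
    tau_observable(model, "efficiency", D = 1, R0 = R0)
}
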