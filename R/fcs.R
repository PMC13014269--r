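#' Intensity correlation from photon streams or binned traces
#'
#' Estimates G_ab(tau) = <dI_a(t) dI_b(t + tau)> / (<I_a><I_b>) from either a
#' [synthesize_photon_stream()] result (photons are binned at the lag-grid
#' spacing) or a list of pre-binned intensity traces
#' `list(a =, b =, dt =)`. The estimator is symmetric in the two channels.
#'
#' @param x A `"photon_stream"` or a list with intensity vectors `a`, `b`
#'   and bin width `dt` (ns).
#' @param channels For photon streams, the two channel labels to correlate,
#'   e.g. `c("D", "A")` for the donor-acceptor cross-correlation.
#' @param lags Uniformly spaced lag grid (ns) starting at 0 or one bin; the
#'   spacing sets the intensity bin width for photon input.
#' @return A [correlation_curve()].
#' @export
correlate <- function(x, channels = c("D", "A"), lags = seq(0, 100, by = 1)) {
  stop_if(length(lags) < 2, "need at least two lags")
  d <- diff(lags)
  stop_if(max(abs(d - d[1])) > 1e-9 * d[1], "lag grid must be uniform")
  bw <- d[1]
  if (inherits(x, "photon_stream")) {
    nb <- ceiling(x$duration / bw)
    ta <- x$times[x$channel == channels[1]]
    tb <- x$times[x$channel == channels[2]]
    stop_if(length(ta) == 0 || length(tb) == 0, "empty channel")
    a <- tabulate(pmin(floor(ta / bw) + 1, nb), nb)
    b <- tabulate(pmin(floor(tb / bw) + 1, nb), nb)
  } else {
    a <- x$a; b <- x$b
    stop_if(is.null(a) || is.null(b), "traces must provide a and b")
    stop_if(abs(x$dt - bw) > 1e-9 * bw,
            "trace bin width must equal the lag spacing")
    nb <- length(a)
  }
  ma <- mean(a); mb <- mean(b)
  stop_if(ma == 0 || mb == 0, "zero mean intensity")
  ks <- round(lags / bw)
  G <- vapply(ks, function(k) {
    if (k >= nb) return(NA_real_)
    n <- nb - k
    mean(a[1:n] * b[(1 + k):nb]) / (ma * mb) - 1
  }, numeric(1))
  same <- identical(channels[1], channels[2]) && inherits(x, "photon_stream")
  if (same && ks[1] == 0) {
    # remove shot-noise (self-pairing) spike at zero lag of autocorrelations
    G[1] <- G[1] - 1 / (ma)
  }
  correlation_curve(lags, G, channel = paste0(tolower(channels), collapse = ""))
}

# Additive nsFCS model in amplitude parameterization:
# G = A0 + A1 e^(-tau/tau_ab) + A2 e^(-tau/tau_cd) + A3 e^(-tau/tau_t);
# A0 = 1/N, Ai = ci/N. Linear in A for fixed times.
nsfcs_design <- function(lags, tau_ab, tau_cd, tau_t) {
  cbind(1, exp(-lags / tau_ab), exp(-lags / tau_cd), exp(-lags / tau_t))
}

amps_to_params <- function(A, tau_ab, tau_cd, tau_t) {
  fcs_params(N = 1 / A[1], c_ab = A[2] / A[1], tau_ab = tau_ab,
             c_cd = A[3] / A[1], tau_cd = tau_cd, c_t = A[4] / A[1],
             tau_t = tau_t)
}

#' Fit the nsFCS model to donor/acceptor correlation curves
#'
#' Least-squares fit of the additive sum-of-exponentials nsFCS model to the
#' dd, aa and da correlation curves with the chain-dynamics time tau_cd
#' shared across the three curves and all amplitudes free in sign
#' (antibunching negative in autocorrelations, the chain-dynamics term
#' anticorrelated in the cross-correlation). Fitting is restricted to a
#' linear window of lag times (default 0-100 ns).
#'
#' @param curves Named list of [correlation_curve()]s (`dd`, `aa`, `da`) on
#'   a common lag grid.
#' @param window Lag window (ns) used for the fit.
#' @param weighted If TRUE, residuals are divided by the curve errors.
#' @param init Optional list with starting `tau_ab`, `tau_cd`, `tau_t` (ns).
#' @return An object of class `"nsfcs_fit"`: `params` (list of
#'   [fcs_params()] per curve), `tau_cd`, `tau_cd_identifiable`, residual
#'   sum of squares and the fit window.
#' @export
fit_nsfcs <- function(curves, window = c(0, 100), weighted = FALSE,
                      init = list(tau_ab = 3, tau_cd = 30, tau_t = 500)) {
  stop_if(!all(c("dd", "aa", "da") %in% names(curves)),
          "curves must contain dd, aa and da")
  lag <- curves$dd$lag_ns
  for (nm in c("aa", "da")) {
    stop_if(!isTRUE(all.equal(curves[[nm]]$lag_ns, lag)),
            "curves must share a common lag grid")
  }
  sel <- lag >= window[1] & lag <= window[2]
  stop_if(!any(sel), "empty fit window")
  lag <- lag[sel]
  Y <- lapply(curves[c("dd", "aa", "da")], function(cc) cc$G[sel])
  W <- lapply(curves[c("dd", "aa", "da")], function(cc) {
    if (weighted && all(is.finite(cc$err[sel])) && all(cc$err[sel] > 0))
      1 / cc$err[sel] else rep(1, sum(sel))
  })
  solve_amps <- function(tau_ab, tau_cd, tau_t) {
    X <- nsfcs_design(lag, tau_ab, tau_cd, tau_t)
    lapply(1:3, function(i) qr.solve(X * W[[i]], Y[[i]] * W[[i]]))
  }
  # parameters: log tau_cd (global), then per curve log tau_ab, log tau_t
  # and 4 amplitudes
  resid_fun <- function(p) {
    tau_cd <- exp(p[1])
    unlist(lapply(1:3, function(i) {
      o <- 1 + (i - 1) * 6
      tau_ab <- exp(p[o + 1]); tau_t <- exp(p[o + 2])
      A <- p[(o + 3):(o + 6)]
      X <- nsfcs_design(lag, tau_ab, tau_cd, tau_t)
      (as.vector(X %*% A) - Y[[i]]) * W[[i]]
    }))
  }
  # variable-projection multi-start: for candidate time scales the model is
  # linear in the amplitudes, so scan a coarse grid of (tau_ab, tau_cd,
  # tau_t), solve the amplitudes by least squares, and refine the best
  # candidate (plus the user initialization) with Levenberg-Marquardt
  rss_of <- function(tau_ab, tau_cd, tau_t) {
    A <- solve_amps(tau_ab, tau_cd, tau_t)
    sum(unlist(lapply(1:3, function(i) {
      X <- nsfcs_design(lag, tau_ab, tau_cd, tau_t)
      ((as.vector(X %*% A[[i]]) - Y[[i]]) * W[[i]])^2
    })))
  }
  cand <- expand.grid(tau_ab = c(1, 3, 8), tau_cd = exp(seq(log(5), log(90),
                                                            length.out = 8)),
                      tau_t = c(150, 400, 1000))
  cand <- rbind(cand, data.frame(tau_ab = init$tau_ab, tau_cd = init$tau_cd,
                                 tau_t = init$tau_t))
  cand$rss <- mapply(rss_of, cand$tau_ab, cand$tau_cd, cand$tau_t)
  run_lm <- function(tau_ab, tau_cd, tau_t) {
    A0 <- solve_amps(tau_ab, tau_cd, tau_t)
    p0 <- c(log(tau_cd), unlist(lapply(1:3, function(i)
      c(log(tau_ab), log(tau_t), A0[[i]]))))
    minpack.lm::nls.lm(p0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, ftol = 1e-15, ptol = 1e-13))
  }
  starts <- unique(rbind(cand[which.min(cand$rss), 1:3],
                         data.frame(tau_ab = init$tau_ab,
                                    tau_cd = init$tau_cd,
                                    tau_t = init$tau_t)))
  fits <- lapply(seq_len(nrow(starts)), function(i)
    run_lm(starts$tau_ab[i], starts$tau_cd[i], starts$tau_t[i]))
  fit <- fits[[which.min(sapply(fits, function(f) f$deviance))]]
  p <- fit$par
  tau_cd <- exp(p[1])
  params <- lapply(1:3, function(i) {
    o <- 1 + (i - 1) * 6
    amps_to_params(p[(o + 3):(o + 6)], exp(p[o + 1]), tau_cd, exp(p[o + 2]))
  })
  names(params) <- c("dd", "aa", "da")
  # identifiability: if dropping the chain-dynamics component fits the data
  # (essentially) equally well, tau_cd is not determined by these curves
  rss_full <- sum(resid_fun(p)^2)
  rss_nocd <- sum(unlist(lapply(1:3, function(i) {
    o <- 1 + (i - 1) * 6
    X <- nsfcs_design(lag, exp(p[o + 1]), 1, exp(p[o + 2]))[, c(1, 2, 4)]
    A <- qr.solve(X * W[[i]], Y[[i]] * W[[i]])
    ((as.vector(X %*% A) - Y[[i]]) * W[[i]])^2
  })))
  identifiable <- (rss_nocd - rss_full) > 1e-8 * (1 + rss_full)
  if (!identifiable) {
    warning("dropping the chain-dynamics term fits equally well: tau_cd unidentifiable")
  }
  structure(list(params = params, tau_cd = tau_cd,
                 tau_cd_identifiable = identifiable,
                 rss = sum(resid_fun(p)^2), window = window,
                 info = fit$info), class = "nsfcs_fit")
}

#' @export
print.nsfcs_fit <- function(x, ...) {
  cat(sprintf("<nsfcs_fit> global tau_cd = %.4g ns (window %g-%g ns, rss = %.3g)%s\n",
              x$tau_cd, x$window[1], x$window[2], x$rss,
              if (!x$tau_cd_identifiable) " [tau_cd unidentifiable]" else ""))
  for (nm in names(x$params)) { cat(" ", nm, ": "); print(x$params[[nm]]) }
  invisible(x)
}

#' Fit the FRET efficiency correlation model
#'
#' Least-squares fit of the multiplicative model
#' g_E(tau) = (1 - c_ab e^(-|tau|/tau_ab)) (1 + c_cd e^(-|tau|/tau_cd))
#' (1 + c_t e^(-|tau|/tau_t)) to an efficiency correlation curve.
#'
#' @param curve A [correlation_curve()] defined at tau >= 0.
#' @param window Lag window (ns).
#' @param weighted If TRUE, residuals are divided by curve errors.
#' @param tau_t_fixed Optional fixed triplet time (ns), used by the global
#'   step of the two-step systematic-uncertainty protocol.
#' @param init Starting values.
#' @return An object of class `"ecorr_fit"` with `params` ([fcs_params()]),
#'   `tau_cd` and the residual sum of squares.
#' @export
fit_efficiency_correlation <- function(curve, window = c(0, 100),
                                       weighted = FALSE, tau_t_fixed = NULL,
                                       init = list(c_ab = 0.5, tau_ab = 3,
                                                   c_cd = 0.3, tau_cd = 30,
                                                   c_t = 0.1, tau_t = 500)) {
  sel <- curve$lag_ns >= window[1] & curve$lag_ns <= window[2]
  stop_if(!any(sel), "empty fit window")
  lag <- curve$lag_ns[sel]
  y <- curve$G[sel]
  w <- if (weighted && all(is.finite(curve$err[sel])) &&
           all(curve$err[sel] > 0)) 1 / curve$err[sel] else rep(1, sum(sel))
  fixed_t <- !is.null(tau_t_fixed)
  resid_fun <- function(p) {
    pr <- fcs_params(N = 1, c_ab = p[1], tau_ab = exp(p[2]), c_cd = p[3],
                     tau_cd = exp(p[4]), c_t = p[5],
                     tau_t = if (fixed_t) tau_t_fixed else exp(p[6]))
    (efficiency_correlation_model(pr, lag) - y) * w
  }
  p0 <- c(init$c_ab, log(init$tau_ab), init$c_cd, log(init$tau_cd),
          init$c_t, if (fixed_t) NULL else log(init$tau_t))
  fit <- minpack.lm::nls.lm(p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-12))
  p <- fit$par
  params <- fcs_params(N = 1, c_ab = p[1], tau_ab = exp(p[2]), c_cd = p[3],
                       tau_cd = exp(p[4]), c_t = p[5],
                       tau_t = if (fixed_t) tau_t_fixed else exp(p[6]))
  structure(list(params = params, tau_cd = params$tau_cd,
                 rss = sum(resid_fun(p)^2), window = window,
                 tau_t_fixed = tau_t_fixed, info = fit$info),
            class = "ecorr_fit")
}

#' @export
print.ecorr_fit <- function(x, ...) {
  cat(sprintf("<ecorr_fit> tau_cd = %.4g ns (rss = %.3g)\n  ", x$tau_cd, x$rss))
  print(x$params)
  invisible(x)
}

#' Two-step systematic uncertainty of efficiency-correlation fits
#'
#' Fits each curve individually, then refits all curves with the triplet
#' time fixed at the mean of the individual estimates (the shared-parameter
#' global step); the per-curve standard deviation of tau_cd between the two
#' steps is reported as the systematic uncertainty.
#'
#' @param curves List of efficiency [correlation_curve()]s.
#' @param ... Passed to [fit_efficiency_correlation()].
#' @return List with `individual`, `global` (fit lists), `tau_cd_individual`,
#'   `tau_cd_global`, `syst` (per-curve sd of the two estimates).
#' @export
fit_efficiency_correlation_batch <- function(curves, ...) {
  ind <- lapply(curves, fit_efficiency_correlation, ...)
  tau_t_shared <- mean(sapply(ind, function(f) f$params$tau_t))
  glob <- lapply(curves, fit_efficiency_correlation,
                 tau_t_fixed = tau_t_shared, ...)
  ti <- sapply(ind, function(f) f$tau_cd)
  tg <- sapply(glob, function(f) f$tau_cd)
  list(individual = ind, global = glob, tau_cd_individual = ti,
       tau_cd_global = tg, tau_t_shared = tau_t_shared,
       syst = apply(rbind(ti, tg), 2, sd))
}

#' Quadrature combination of uncertainty components
#'
#' @param components Non-negative uncertainty components (e.g. statistical
#'   and systematic contributions of two analysis routes).
#' @return Square root of the sum of squares.
#' @examples
#' combine_uncertainty(c(3, 4)) # 5
#' @export
combine_uncertainty <- function(components) {
  stop_if(any(components < 0), "components must be non-negative")
  sqrt(sum(components^2))
}

#' Convert efficiency correlation times to a chain reconfiguration time
#'
#' Applies the SAW-nu conversion factor theta = tau_r / tau_E to measured
#' chain-dynamics correlation times: nu is inferred from the mean transfer
#' efficiency, theta evaluated on the corresponding SAW-nu distance
#' distribution, and tau_r taken as the arithmetic mean of the converted
#' nsFCS and efficiency-correlation values when both are supplied.
#' Statistical uncertainties default to 10% of each measured time;
#' systematic components default to zero and should be supplied from the
#' fit-window / shared-parameter protocols. All four components are
#' propagated through the conversion and combined in quadrature.
#'
#' @param tau_E_nsfcs,tau_E_ecorr Measured chain-dynamics times (ns) from
#'   the nsFCS and efficiency-correlation routes (at least one).
#' @param E Mean transfer efficiency, in (0, 1).
#' @param R0 Foerster radius (nm).
#' @param n_segments,b Chain calibration passed to [saw_nu_model()].
#' @param errors List with components `nsfcs_stat`, `nsfcs_syst`,
#'   `fret_stat`, `fret_syst` (ns, on the tau_E scale); missing statistical
#'   components default to 10% of the corresponding tau_E.
#' @param theta_override Force a conversion factor (e.g. 1 to report tau_E
#'   itself).
#' @return An object of class `"reconfig_result"`.
#' @export
reconfiguration_time <- function(tau_E_nsfcs = NULL, tau_E_ecorr = NULL, E,
                                 R0 = 6.0, n_segments = 65, b = 0.55,
                                 errors = list(), theta_override = NULL) {
  stop_if(is.null(tau_E_nsfcs) && is.null(tau_E_ecorr),
          "supply at least one measured correlation time")
  stop_if(E <= 0 || E >= 1, "E must lie strictly in (0, 1)")
  taus <- c(nsfcs = tau_E_nsfcs, ecorr = tau_E_ecorr)
  stop_if(any(taus <= 0), "correlation times must be positive")
  if (is.null(theta_override)) {
    nu <- infer_nu(E, R0 = R0, n_segments = n_segments, b = b)
    model <- saw_nu_model(nu, n_segments = n_segments, b = b)
    theta <- conversion_factor(model, R0 = R0)
  } else {
    nu <- NA_real_; theta <- theta_override
  }
  tau_r_each <- theta * taus
  tau_r <- mean(tau_r_each)
  comp <- c(
    nsfcs_syst = if (!is.null(tau_E_nsfcs))
      theta * (errors$nsfcs_syst %||% 0) else 0,
    nsfcs_stat = if (!is.null(tau_E_nsfcs))
      theta * (errors$nsfcs_stat %||% (0.1 * tau_E_nsfcs)) else 0,
    fret_syst = if (!is.null(tau_E_ecorr))
      theta * (errors$fret_syst %||% 0) else 0,
    fret_stat = if (!is.null(tau_E_ecorr))
      theta * (errors$fret_stat %||% (0.1 * tau_E_ecorr)) else 0)
  structure(list(tau_E = taus, nu = nu, theta = theta,
                 tau_r_each = tau_r_each, tau_r = tau_r,
                 uncertainty_components = comp,
                 delta_tau_r = combine_uncertainty(comp), E = E, R0 = R0),
            class = "reconfig_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reconfig_result <- function(x, ...) {
  cat(sprintf(
    "<reconfig_result> E = %.3f -> nu = %s, theta = %.3f; tau_r = %.2f +/- %.2f ns\n",
    x$E, if (is.na(x$nu)) "(override)" else sprintf("%.3f", x$nu),
    x$theta, x$tau_r, x$delta_tau_r))
  invisible(x)
}

#' Viscosity dependence and internal-friction intercept
#'
#' Weighted linear fit tau_r = tau_i + s (eta/eta0) to a solvent-viscosity
#' series; the intercept tau_i at zero relative viscosity is the
#' internal-friction time. A negative point estimate is reported as
#' consistent with zero together with its confidence interval.
#'
#' @param eta_rel Relative viscosities eta/eta0 (>= 3 points).
#' @param tau_r Reconfiguration times (ns).
#' @param errors Optional per-point uncertainties (ns); weights 1/err^2.
#' @param level Confidence level for the intercept interval.
#' @return List with `slope`, `intercept`, `intercept_ci`,
#'   `consistent_with_zero` and the underlying `lm` fit.
#' @export
viscosity_intercept <- function(eta_rel, tau_r, errors = NULL,
                                level = 0.95) {
  stop_if(length(eta_rel) < 3, "need at least 3 viscosity points")
  w <- if (is.null(errors)) rep(1, length(eta_rel)) else 1 / errors^2
  fit <- lm(tau_r ~ eta_rel, weights = w)
  ci <- suppressWarnings(stats::confint(fit, level = level))[1, ]
  icpt <- coef(fit)[[1]]
  list(slope = coef(fit)[[2]], intercept = icpt,
       intercept_ci = unname(ci),
       consistent_with_zero = ci[1] <= 0 && ci[2] >= 0, fit = fit)
}
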