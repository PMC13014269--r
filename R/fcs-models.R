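#' Correlation-model parameter set
#'
#' Parameters of the closed-form fluorescence correlation models: `N` is the
#' normalization (mean number of molecules in the confocal volume), and each
#' (amplitude, time) pair describes one relaxation component -- photon
#' antibunching (`c_ab`, `tau_ab`), chain dynamics (`c_cd`, `tau_cd`) and
#' triplet blinking (`c_t`, `tau_t`). All times in ns.
#'
#' @param N Normalization factor (> 0); ignored by the efficiency-correlation
#'   model, which is normalized to 1.
#' @param c_ab,tau_ab Antibunching amplitude and time scale.
#' @param c_cd,tau_cd Chain-dynamics amplitude and time scale.
#' @param c_t,tau_t Triplet amplitude and time scale.
#' @return An object of class `"fcs_params"`.
#' @export
fcs_params <- function(N = 1, c_ab = 0, tau_ab = 3, c_cd = 0, tau_cd = 50,
                       c_t = 0, tau_t = 1000) {
  stop_if(any(c(tau_ab, tau_cd, tau_t) <= 0), "time scales must be positive")
  stop_if(N <= 0, "N must be positive")
  structure(list(N = N, c_ab = c_ab, tau_ab = tau_ab, c_cd = c_cd,
                 tau_cd = tau_cd, c_t = c_t, tau_t = tau_t),
            class = "fcs_params")
}

#' @export
print.fcs_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<fcs_params> N = %.4g | antibunching c = %.4g, tau = %.4g ns | ",
    "chain c = %.4g, tau = %.4g ns | triplet c = %.4g, tau = %.4g ns\n"),
    x$N, x$c_ab, x$tau_ab, x$c_cd, x$tau_cd, x$c_t, x$tau_t))
  invisible(x)
}

#' Closed-form correlation models
#'
#' `nsfcs_model` is the additive nanosecond-FCS form
#' G(tau) = (1/N) (1 + c_ab exp(-tau/tau_ab) + c_cd exp(-tau/tau_cd)
#' + c_t exp(-tau/tau_t)); with all amplitudes zero it is identically 1/N.
#' `efficiency_correlation_model` is the multiplicative FRET-efficiency
#' correlation form g_E(tau) = (1 - c_ab e)(1 + c_cd e)(1 + c_t e), which is
#' identically 1 with all amplitudes zero.
#'
#' @param params An [fcs_params()].
#' @param lags Lag times (ns), non-negative.
#' @return Model values at `lags`.
#' @export
nsfcs_model <- function(params, lags) {
  with(params, (1 + c_ab * exp(-lags / tau_ab) + c_cd * exp(-lags / tau_cd) +
                  c_t * exp(-lags / tau_t)) / N)
}

#' @rdname nsfcs_model
#' @export
efficiency_correlation_model <- function(params, lags) {
  a <- abs(lags)
  with(params, (1 - c_ab * exp(-a / tau_ab)) * (1 + c_cd * exp(-a / tau_cd)) *
         (1 + c_t * exp(-a / tau_t)))
}

#' Correlation curve container
#'
#' @param lag_ns Lag times (ns), strictly increasing.
#' @param G Correlation amplitudes.
#' @param err Optional per-lag standard errors (>= 0).
#' @param channel Channel pair label, e.g. "dd", "aa", "da", "E".
#' @return An object of class `"correlation_curve"` (also a data.frame).
#' @export
correlation_curve <- function(lag_ns, G, err = NA_real_, channel = "") {
  stop_if(any(diff(lag_ns) <= 0), "lags must be strictly increasing")
  stop_if(any(!is.na(err) & err < 0), "errors must be non-negative")
  structure(data.frame(lag_ns = lag_ns, G = G, err = err),
            channel = channel, class = c("correlation_curve", "data.frame"))
}

#' Synthesize a correlation curve from a closed-form model
#'
#' Evaluates the nsFCS (additive) or efficiency-correlation (multiplicative)
#' model on a lag grid and adds i.i.d. Gaussian noise of standard deviation
#' `noise_sd`; `noise_sd = 0` returns the exact model.
#'
#' @param model `"nsfcs"` or `"efficiency"`.
#' @param params An [fcs_params()].
#' @param lags Non-negative, increasing lag grid (ns).
#' @param noise_sd Amplitude of the additive Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return A [correlation_curve()]; `err` is set to `noise_sd`.
#' @export
synthesize_correlation_curve <- function(model = c("nsfcs", "efficiency"),
                                         params, lags, noise_sd = 0,
                                         seed = NULL) {
  model <- match.arg(model)
  stop_if(noise_sd < 0, "noise_sd must be non-negative")
  stop_if(any(lags < 0) || any(diff(lags) <= 0),
          "lags must be non-negative and increasing")
  g <- if (model == "nsfcs") nsfcs_model(params, lags)
       else efficiency_correlation_model(params, lags)
  if (noise_sd > 0) {
    g <- g + with_seed(seed, rnorm(length(lags), sd = noise_sd))
  }
  correlation_curve(lags, g, err = if (noise_sd > 0) noise_sd else NA_real_,
                    channel = if (model == "nsfcs") "dd" else "E")
}
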