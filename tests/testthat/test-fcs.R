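nsfcs_truth <- list(
  dd = fcs_params(N = 0.5, c_ab = -0.8, tau_ab = 3, c_cd = 0.35, tau_cd = 40,
                  c_t = 0.15, tau_t = 250),
  aa = fcs_params(N = 0.7, c_ab = -0.7, tau_ab = 3, c_cd = 0.30, tau_cd = 40,
                  c_t = 0.12, tau_t = 250),
  da = fcs_params(N = 0.6, c_ab = 0.5, tau_ab = 3, c_cd = -0.25, tau_cd = 40,
                  c_t = 0.10, tau_t = 250))

test_that("the correlator vanishes without intensity fluctuations", {
  tr <- list(a = rep(5, 5000), b = rep(3, 5000), dt = 1)
  cc <- correlate(tr, lags = seq(0, 50, by = 1))
  expect_lt(max(abs(cc$G)), 1e-12)
  set.seed(1)
  ps <- synthesize_photon_stream(rep(0.5, 3e5), 1, mean_rate = 0.4,
                                 seed = 2)
  ca <- correlate(ps, c("D", "D"), lags = seq(0, 80, by = 2))
  expect_lt(max(abs(ca$G[-1])), 0.05) # homogeneous Poisson: no correlation
})

test_that("telegraph-modulated streams give the telegraph correlation time", {
  k <- 0.02 # per-ns switch rate; correlation time 1/(2k) = 25 ns
  set.seed(3)
  dw <- rexp(1.2e5, k)
  tsw <- cumsum(dw)
  state <- rep(c(0, 1), length.out = length(tsw) + 1)
  dt <- 0.5
  nT <- floor(tsw[length(tsw)] / dt) - 1
  E <- 0.2 + 0.6 * state[findInterval((1:nT) * dt, tsw) + 1]
  ps <- synthesize_photon_stream(E, dt, mean_rate = 0.08, seed = 4)
  cc <- correlate(ps, c("D", "A"), lags = seq(0, 150, by = 1))
  # anticorrelated single exponential: fit log(-G) over a clean range
  sel <- cc$lag_ns >= 2 & cc$lag_ns <= 60 & cc$G < 0
  fitl <- lm(log(-cc$G[sel]) ~ cc$lag_ns[sel])
  tau_fit <- -1 / coef(fitl)[[2]]
  expect_lt(abs(tau_fit - 25) / 25, 0.10)
})

test_that("noiseless nsFCS curves refit exactly with a global tau_cd", {
  lags <- seq(0, 500, by = 1)
  curves <- lapply(nsfcs_truth, function(p)
    synthesize_correlation_curve("nsfcs", p, lags))
  fit <- fit_nsfcs(curves, window = c(0, 500))
  expect_lt(abs(fit$tau_cd - 40) / 40, 1e-6)
  for (nm in names(nsfcs_truth)) {
    expect_lt(abs(fit$params[[nm]]$N - nsfcs_truth[[nm]]$N) /
                nsfcs_truth[[nm]]$N, 1e-6)
    expect_lt(abs(fit$params[[nm]]$c_cd - nsfcs_truth[[nm]]$c_cd) /
                abs(nsfcs_truth[[nm]]$c_cd), 1e-5)
  }
  expect_true(fit$tau_cd_identifiable)
  # round trip through the synthesizer at recovered parameters
  back <- synthesize_correlation_curve("nsfcs", fit$params$dd, lags)
  expect_lt(max(abs(back$G - curves$dd$G)), 1e-8)
})

test_that("noisy nsFCS recovery is consistent over Monte-Carlo replicates", {
  lags <- seq(0, 500, by = 2)
  est <- sapply(1:8, function(s) {
    cN <- lapply(nsfcs_truth, function(p)
      synthesize_correlation_curve("nsfcs", p, lags, noise_sd = 0.01,
                                   seed = 1000 + s))
    fit_nsfcs(cN, window = c(0, 500))$tau_cd
  })
  expect_lt(abs(mean(est) - 40), 3 * sd(est) / sqrt(length(est)) + sd(est))
})

test_that("zero chain-dynamics amplitude is flagged as unidentifiable", {
  lags <- seq(0, 400, by = 2)
  p0 <- fcs_params(N = 1, c_ab = -0.5, tau_ab = 3, c_cd = 0, c_t = 0.1,
                   tau_t = 250)
  curves <- list(dd = synthesize_correlation_curve("nsfcs", p0, lags),
                 aa = synthesize_correlation_curve("nsfcs", p0, lags),
                 da = synthesize_correlation_curve("nsfcs", p0, lags))
  expect_warning(fit <- fit_nsfcs(curves, window = c(0, 400)),
                 "unidentifiable")
  expect_false(fit$tau_cd_identifiable)
})

test_that("the efficiency-correlation model refits exactly", {
  pe <- fcs_params(N = 1, c_ab = 0.6, tau_ab = 3, c_cd = 0.28, tau_cd = 35,
                   c_t = 0.08, tau_t = 250)
  lags <- seq(0, 500, by = 1)
  ce <- synthesize_correlation_curve("efficiency", pe, lags)
  fe <- fit_efficiency_correlation(ce, window = c(0, 500))
  for (f in c("c_ab", "tau_ab", "c_cd", "tau_cd", "c_t", "tau_t")) {
    expect_lt(abs(fe$params[[f]] - pe[[f]]) / abs(pe[[f]]), 1e-6)
  }
  # product form ~ additive form when amplitudes are small
  ps <- fcs_params(N = 1, c_ab = 0.01, tau_ab = 3, c_cd = 0.02, tau_cd = 35,
                   c_t = 0.005, tau_t = 250)
  prod_form <- efficiency_correlation_model(ps, lags)
  add_form <- 1 - ps$c_ab * exp(-lags / 3) + ps$c_cd * exp(-lags / 35) +
    ps$c_t * exp(-lags / 250)
  expect_lt(max(abs(prod_form - add_form)), 5 * 0.02^2)
})

test_that("the batch two-step protocol reports a systematic spread", {
  lags <- seq(0, 500, by = 2)
  mk <- function(tau_t, seed) synthesize_correlation_curve(
    "efficiency",
    fcs_params(N = 1, c_ab = 0.5, tau_ab = 3, c_cd = 0.3, tau_cd = 30,
               c_t = 0.1, tau_t = tau_t),
    lags, noise_sd = 0.004, seed = seed)
  curves <- list(mk(220, 1), mk(280, 2), mk(340, 3))
  bt <- fit_efficiency_correlation_batch(curves, window = c(0, 500))
  expect_length(bt$syst, 3)
  expect_true(all(bt$syst >= 0))
  expect_true(all(abs(bt$tau_cd_individual - 30) / 30 < 0.2))
})

test_that("uncertainty components combine in quadrature", {
  expect_equal(combine_uncertainty(c(3, 4, 0, 0)), 5)
  expect_equal(combine_uncertainty(c(1, 1, 1, 1)), 2)
  expect_equal(combine_uncertainty(c(0, 0, 7, 0)), 7)
  expect_error(combine_uncertainty(c(1, -1)), "non-negative")
})

test_that("reconfiguration-time conversion averages the two routes", {
  r0 <- reconfiguration_time(tau_E_nsfcs = 28, tau_E_ecorr = 32, E = 0.5,
                             theta_override = 1)
  expect_equal(r0$tau_r, 30)
  expect_equal(unname(r0$uncertainty_components["nsfcs_stat"]), 2.8)
  r1 <- reconfiguration_time(tau_E_nsfcs = 20, E = 0.6)
  expect_gt(r1$theta, 0)
  expect_equal(r1$tau_r, r1$theta * 20)
  expect_gte(r1$delta_tau_r,
             max(r1$uncertainty_components) - 1e-12)
  expect_error(reconfiguration_time(E = 0.5), "at least one")
  expect_error(reconfiguration_time(tau_E_nsfcs = 10, E = 1.2), "E must")
})

test_that("viscosity series extrapolate to the internal-friction intercept", {
  eta <- c(1, 1.05, 1.14, 1.31, 1.76) # 0-20% glycerol scale
  v0 <- viscosity_intercept(eta, 12 * eta)
  expect_lt(abs(v0$intercept), 1e-10)
  v5 <- viscosity_intercept(eta, 5 + 12 * eta)
  expect_equal(v5$intercept, 5, tolerance = 1e-10)
  expect_equal(v5$slope, 12, tolerance = 1e-10)
  expect_error(viscosity_intercept(c(1, 1.1), c(10, 11)), "3")
  # Monte-Carlo coverage with zero-truth intercept
  set.seed(8)
  hits <- mean(replicate(300, {
    tau <- 12 * eta + rnorm(5, 0, 0.5)
    v <- viscosity_intercept(eta, tau, errors = rep(0.5, 5))
    v$consistent_with_zero
  }))
  expect_gte(hits, 0.90)
})
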