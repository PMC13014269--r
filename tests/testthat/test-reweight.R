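test_that("possible salt bridges respect the separation rule", {
  expect_equal(possible_salt_bridges("KAAE"), 1)
  expect_equal(possible_salt_bridges("KAE"), 0)
  expect_equal(possible_salt_bridges("AAAAAA"), 0)
  expect_equal(possible_salt_bridges("EAAAKAAAR"), 2) # E-K (4), E-R (8)
  expect_equal(possible_salt_bridges("DKAAAKD"), 2) # D1-K6, K2-D7
  expect_error(possible_salt_bridges("AXZ"), "unknown")
})

test_that("the hysteresis contact automaton follows its two thresholds", {
  expect_equal(contact_states(c(0.50, 0.36, 0.60, 0.79, 0.85, 0.37)),
               c(0, 1, 1, 1, 0, 1))
  expect_equal(contact_states(rep(0.9, 5)), rep(0, 5))
  expect_equal(contact_states(rep(0.2, 5)), rep(1, 5))
  expect_equal(contact_states(c(0.5, 0.5)), c(0, 0))
  expect_error(contact_states(c(0.5), form_cut = 0.9, break_cut = 0.8),
               "smaller")
})

test_that("reweighting produces normalized Boltzmann-tilted weights", {
  ens <- weighted_ensemble(c(0.5, 0.7), rbind(c(0L, 0L, 0L, 0L),
                                              c(1L, 0L, 0L, 0L)))
  w0 <- reweight_weights(ens, salt_bridge_params(eps_sb = 0))
  expect_equal(w0, c(0.5, 0.5))
  w <- reweight_weights(ens, salt_bridge_params(eps_sb = log(2)))
  expect_equal(w, c(2 / 3, 1 / 3))
  one <- weighted_ensemble(0.5, matrix(3L, 1, 4))
  expect_equal(reweight_weights(one, salt_bridge_params(eps_sb = 5)), 1)
  # overflow guard: huge counts and energies still normalize
  big <- weighted_ensemble(c(0.2, 0.8), rbind(rep(500L, 4), rep(0L, 4)))
  wb <- reweight_weights(big, salt_bridge_params(eps_sb = 10))
  expect_equal(sum(wb), 1)
  expect_false(anyNA(wb))
})

test_that("reweighted averages stay inside the frame range and ESS shrinks", {
  syn <- small_ensembles(3, 2000, eps_sb = 0.5, seed = 1)
  e <- syn$ensembles[[1]]
  ess_prev <- Inf
  for (eps in c(0, 0.5, 1, 2)) {
    w <- reweight_weights(e, salt_bridge_params(eps_sb = eps))
    expect_lt(abs(sum(w) - 1), 1e-10)
    Ew <- sum(w * e$E)
    expect_gte(Ew, min(e$E)); expect_lte(Ew, max(e$E))
    ess <- effective_sample_size(w)
    expect_lte(ess, ess_prev + 1e-9)
    ess_prev <- ess
  }
})

test_that("analytical chi-square gradient matches central finite differences", {
  syn <- small_ensembles(4, 1500, eps_sb = 0.4, seed = 2)
  for (sig in list(NULL, 0.03)) {
    par0 <- salt_bridge_params(0.3, 0.8, 0.1, 0.5)
    g <- chi2_and_grad(syn$ensembles, syn$E_expt, par0, sigma = sig)$grad
    h <- 1e-5
    fd <- sapply(1:4, function(i) {
      ep <- par0$eps; em <- par0$eps
      ep[i] <- ep[i] + h; em[i] <- em[i] - h
      cp <- chi2_and_grad(syn$ensembles, syn$E_expt,
                          salt_bridge_params(ep[1], ep[2], ep[3], ep[4]),
                          sigma = sig)$chi2
      cm <- chi2_and_grad(syn$ensembles, syn$E_expt,
                          salt_bridge_params(em[1], em[2], em[3], em[4]),
                          sigma = sig)$chi2
      (cp - cm) / (2 * h)
    })
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-6)
  }
  # perfect fit: zero chi2, zero gradient
  z <- chi2_and_grad(syn$ensembles,
                     sapply(syn$ensembles, function(e) sum(e$weights * e$E)),
                     salt_bridge_params(eps_sb = 0))
  expect_equal(z$chi2, 0)
  expect_lt(max(abs(z$grad)), 1e-12)
})

test_that("the uniform scan finds the generating perturbation", {
  syn <- small_ensembles(6, 4000, eps_sb = 0.5, seed = 3)
  sc <- scan_uniform(syn$ensembles, syn$E_expt, grid = seq(0, 2, by = 0.05))
  expect_lt(abs(sc$eps_opt - 0.5), 0.05 + 1e-12)
  i <- which.min(sc$chi2)
  expect_gt(sc$chi2[i - 1] + sc$chi2[i + 1] - 2 * sc$chi2[i], 0) # convex
  syn0 <- small_ensembles(6, 4000, eps_sb = 0, seed = 4)
  expect_equal(scan_uniform(syn0$ensembles, syn0$E_expt)$eps_opt, 0)
})

test_that("regularized descent shrinks with gamma and respects symmetry", {
  syn <- small_ensembles(8, 3000, eps_sb = 0.5, seed = 5)
  fit <- fit_four_param(syn$ensembles, syn$E_expt, gamma = 1, sigma = 0.03,
                        max_iter = 2000)
  expect_true(fit$converged)
  # uniform generator: components roughly equal
  expect_lt(diff(range(fit$params$eps)), 0.4)
  # gamma -> large drives the component sum toward zero
  fitL <- fit_four_param(syn$ensembles, syn$E_expt, gamma = 1e6,
                         sigma = 0.03, max_iter = 2000)
  expect_lt(abs(sum(fitL$params$eps)), abs(sum(fit$params$eps)) / 10)
  # tied uniform scan and free four-parameter fit agree near the optimum
  sc <- scan_uniform(syn$ensembles, syn$E_expt, sigma = 0.03)
  expect_lt(abs(mean(fit$params$eps) - sc$eps_opt), 0.15)
})

test_that("Bayesian reweighting balances prior and targets", {
  set.seed(6)
  E <- pmin(pmax(rnorm(1500, 0.6, 0.12), 0.01), 0.99)
  ens <- weighted_ensemble(E, matrix(0L, 1500, 4))
  m1 <- mean(E); v <- mean(E^2) - m1^2
  f0 <- bioen_fit(ens, m1, v, theta = 10)
  expect_lt(f0$kl, 1e-8)
  expect_lt(max(abs(f0$weights - 1 / 1500)) * 1500, 1e-4)
  # tilted targets, theta -> 0: hard-constraint limit
  wst <- exp(3 * E); wst <- wst / sum(wst)
  tE <- sum(wst * E); tV <- sum(wst * E^2) - tE^2
  fh <- bioen_fit(ens, tE, tV, theta = 1e-2)
  expect_lt(abs(fh$E - tE), 2e-3)
  expect_lt(abs(fh$varE - tV), 2e-3)
  # moderate theta: within stated uncertainties, minimal KL in its family
  fm <- bioen_fit(ens, tE, tV, theta = 5)
  expect_lt(abs(fm$E - tE), 0.03)
  expect_lt(abs(fm$varE - tV), 0.02)
  expect_true(fm$kl >= 0)
  # infeasible target flagged
  fi <- bioen_fit(ens, 1.5, 0.01, theta = 1)
  expect_true(fi$infeasible)
  expect_error(bioen_fit(weighted_ensemble(c(.1, .2), matrix(0L, 2, 4)),
                         0.15, 0.01), "10 frames")
})

test_that("dual-space BioEn solution matches direct simplex minimization", {
  set.seed(7)
  ns <- 30
  Es <- runif(ns, 0.2, 0.9)
  ens <- weighted_ensemble(Es, matrix(0L, ns, 4))
  tE <- 0.55; tV <- 0.03; th <- 2
  fb <- bioen_fit(ens, tE, tV, theta = th)
  objv <- function(w) {
    m <- sum(w * Es); vv <- sum(w * Es^2) - m^2
    th * sum(w * log(pmax(w, 1e-300) * ns)) +
      0.5 * (((m - tE) / 0.03)^2 + ((vv - tV) / 0.02)^2)
  }
  oo <- optim(rep(0, ns), function(lw) {
    w <- exp(lw - max(lw)); objv(w / sum(w))
  }, method = "BFGS", control = list(maxit = 3000, reltol = 1e-14))
  expect_lt(objv(fb$weights) - oo$value, 1e-6)
})
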