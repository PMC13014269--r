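test_that("discretization covers the sampled range with equal bins", {
  v <- seq(0, 1, length.out = 3000)
  d <- discretize(v, 30)
  occ <- tabulate(d$indices, 30)
  expect_lt(max(abs(occ - 100)), 2)
  expect_equal(d$indices[1], 1L)
  expect_equal(d$indices[length(v)], 30L)
  expect_equal(length(d$grid$edges), 31)
  expect_lt(max(abs(diff(d$grid$edges) - d$grid$h)), 1e-12)
  # re-discretizing bin centers is idempotent
  d2 <- discretize(d$grid$centers, 30)
  expect_equal(d2$indices, 1:30)
  expect_error(discretize(rep(1, 10)), "constant")
})

test_that("transition counting satisfies the counting identities", {
  idx <- rep(5L, 100)
  ct <- count_transitions(idx, dt_out = 1, lags = 10, n_bins = 30)
  expect_equal(sum(ct$mats[[1]]), 90)
  expect_equal(ct$mats[[1]][5, 5], 90)
  alt <- rep(c(1L, 2L), 50)
  ca <- count_transitions(alt, dt_out = 1, lags = 1, n_bins = 2)
  expect_equal(diag(ca$mats[[1]]), c(0, 0))
  expect_equal(sum(ca$mats[[1]]), 99)
  expect_error(count_transitions(alt, dt_out = 1, lags = 1.5, n_bins = 2),
               "multiple")
  expect_error(count_transitions(alt, dt_out = 1, lags = 200, n_bins = 2),
               "longer")
})

test_that("the rate matrix obeys detailed balance with Boltzmann stationarity", {
  rm10 <- random_rate_matrix(10, seed = 5)
  Kp <- rm10$K %*% diag(rm10$p_eq)
  expect_lt(max(abs(Kp - t(Kp))), 1e-12)
  expect_lt(max(abs(colSums(rm10$K))), 1e-12)
  expect_true(all(rm10$K[row(rm10$K) != col(rm10$K)] >= 0))
  expect_lt(abs(rm10$lambda[1]), 1e-10)
  expect_true(all(rm10$lambda[-1] < 0))
  # propagator is stochastic and leaves exp(-F)/Z invariant
  P <- propagator(rm10, 5)
  expect_lt(max(abs(colSums(P) - 1)), 1e-10)
  expect_lt(max(abs(P %*% rm10$p_eq - rm10$p_eq)), 1e-10)
  # flat landscape: symmetric tridiagonal with off-diagonals D/h^2
  nb <- 6
  grid <- structure(list(edges = seq(0, 0.6, by = 0.1),
                         centers = seq(0.05, 0.55, by = 0.1), h = 0.1,
                         n_bins = 6L), class = "bin_grid")
  rf <- build_rate_matrix(diffusion_landscape(rep(0, 6), 0.2, grid))
  expect_equal(rf$K[cbind(2:6, 1:5)], rep(0.2 / 0.01, 5))
  expect_equal(rf$K, t(rf$K))
})

test_that("log-likelihood is linear in counts and vanishes without data", {
  rm10 <- random_rate_matrix(10, seed = 6)
  empty <- structure(list(lags_ns = 5, lag_frames = 5,
                          mats = list(matrix(0L, 10, 10)), n_bins = 10L,
                          dt_out = 1), class = "transition_counts")
  expect_equal(log_likelihood(empty, rm10), 0)
  set.seed(7)
  N <- matrix(rpois(100, 3), 10, 10)
  cnt <- structure(list(lags_ns = 5, lag_frames = 5, mats = list(N),
                        n_bins = 10L, dt_out = 1),
                   class = "transition_counts")
  cnt2 <- cnt; cnt2$mats[[1]] <- 2 * N
  expect_equal(log_likelihood(cnt2, rm10), 2 * log_likelihood(cnt, rm10))
})

test_that("likelihood peaks at the generating landscape on exact counts", {
  # expected counts from the true propagator; profile over a D family
  grid <- structure(list(edges = seq(0, 1, length.out = 11),
                         centers = seq(0.05, 0.95, by = 0.1), h = 0.1,
                         n_bins = 10L), class = "bin_grid")
  F <- 2 * (grid$centers - 0.5)^2 * 10
  Dtrue <- 0.05
  rmt <- build_rate_matrix(diffusion_landscape(F, Dtrue, grid))
  P <- propagator(rmt, 2)
  N <- round(1e6 * P %*% diag(rmt$p_eq))
  cnt <- structure(list(lags_ns = 2, lag_frames = 2, mats = list(N),
                        n_bins = 10L, dt_out = 1),
                   class = "transition_counts")
  Ds <- seq(0.02, 0.10, by = 0.005)
  ll <- sapply(Ds, function(D) {
    log_likelihood(cnt, build_rate_matrix(diffusion_landscape(F, D, grid)))
  })
  expect_equal(Ds[which.max(ll)], Dtrue)
})

test_that("eigen-decomposition C(t) and tau match matrix-exponential oracles", {
  skip_if_not_installed("Matrix")
  for (seed in 1:5) {
    rm10 <- random_rate_matrix(10, seed = seed)
    r <- rm10$grid$centers; p <- rm10$p_eq
    mu <- sum(r * p); v <- sum(r^2 * p) - mu^2
    ts <- c(0.003, 0.03, 0.3, 1.5)
    cf <- correlation_function(rm10, t = ts)
    oracle <- sapply(ts, function(tt) {
      P <- as.matrix(Matrix::expm(rm10$K * tt))
      (sum(r * (P %*% (p * r))) - mu^2) / v
    })
    expect_lt(max(abs(cf$C - oracle)), 1e-8)
    # tau equals the time integral of C
    tg <- seq(0, -60 / rm10$lambda[2], length.out = 60001)
    Ci <- correlation_function(rm10, t = tg)
    expect_lt(abs(correlation_time(rm10) - dynabuffer:::trapz(tg, Ci$C)) /
                correlation_time(rm10), 1e-5)
    expect_equal(correlation_function(rm10, t = 0)$C[1], 1)
    expect_true(all(diff(correlation_function(
      rm10, t = seq(0, 1, by = 0.01))$C) <= 1e-12))
  }
})

test_that("a two-bin symmetric system has the textbook relaxation", {
  grid <- structure(list(edges = c(-0.5, 0.5, 1.5), centers = c(0, 1),
                         h = 1, n_bins = 2L), class = "bin_grid")
  rm2 <- build_rate_matrix(diffusion_landscape(c(0, 0), 0.05, grid))
  expect_equal(rm2$K[2, 1], 0.05)
  cf <- correlation_function(rm2, t = c(0, 5, 10))
  expect_equal(cf$C, exp(-0.1 * c(0, 5, 10)), tolerance = 1e-12)
  expect_equal(correlation_time(rm2), 10, tolerance = 1e-12)
})

test_that("fine discretization of a harmonic well approaches Var[r]/D", {
  taus <- sapply(c(30, 60), function(nb) {
    edges <- seq(0, 4, length.out = nb + 1)
    ctr <- (edges[-1] + edges[-(nb + 1)]) / 2
    g <- structure(list(edges = edges, centers = ctr, h = edges[2] - edges[1],
                        n_bins = as.integer(nb)), class = "bin_grid")
    correlation_time(build_rate_matrix(
      diffusion_landscape(0.5 * 4 * (ctr - 2)^2, 0.1, g)))
  })
  expect_lt(abs(taus[2] - 2.5) / 2.5, 0.02)
  expect_lt(abs(taus[2] - 2.5), abs(taus[1] - 2.5)) # refining improves
})

test_that("landscape fitting recovers constant-D ground truth", {
  tr <- ou_traj(n_steps = 1e7, seed = 8, dt = 0.005, stride = 20)
  di <- discretize(tr, 30)
  cnt <- count_transitions(di$indices, tr$dt_out, lags = c(0.5, 1, 2))
  fit <- fit_landscape(cnt, di$grid, mode = "constant_D", n_steps = 4000,
                       seed = 9)
  expect_lt(abs(fit$ml$D - 0.1) / 0.1, 0.10)
  ctr <- di$grid$centers
  r2 <- summary(lm(fit$ml$F ~ I(2 * (ctr - 2)^2)))$r.squared
  expect_gt(r2, 0.98)
  # single-lag fits agree with the simultaneous fit
  f1 <- fit_landscape(count_transitions(di$indices, tr$dt_out, lags = 1),
                      di$grid, mode = "constant_D", n_steps = 3000,
                      seed = 10)
  expect_lt(abs(f1$ml$D - fit$ml$D) / fit$ml$D, 0.10)
})
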