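#' Discretize a distance trajectory into equal-width bins
#'
#' Splits the sampled range into `n_bins` equal-size, nonoverlapping bins
#' between the minimum and maximum sampled value; the maximum sample is
#' assigned to the last bin (closed upper edge).
#'
#' @param traj A [distance_trajectory()] (or numeric vector) with at least
#'   two distinct values.
#' @param n_bins Number of bins (default 30).
#' @return List with `grid` (class `"bin_grid"`: `edges`, `centers`, `h`,
#'   `n_bins`) and `indices` (integer bin index per frame).
#' @export
discretize <- function(traj, n_bins = 30) {
  v <- if (inherits(traj, "distance_trajectory")) traj$values else traj
  rng <- range(v)
  stop_if(rng[1] == rng[2], "constant trajectory cannot be discretized")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- edges[2] - edges[1]
  idx <- pmin(floor((v - rng[1]) / h) + 1L, n_bins)
  grid <- structure(list(edges = edges,
                         centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                         h = h, n_bins = as.integer(n_bins)),
                    class = "bin_grid")
  list(grid = grid, indices = as.integer(idx))
}

#' Count lagged bin-to-bin transitions
#'
#' Sliding-origin transition counts N_ji(lag) = number of frame pairs with
#' bin i at t and bin j at t + lag; every frame with a full lag ahead is an
#' origin, so the total count per lag is n_frames - lag_frames.
#'
#' @param indices Integer bin index series (from [discretize()]).
#' @param dt_out Frame spacing (ns).
#' @param lags Lag times (ns; default 5, 10, 20). Converted to frames by
#'   rounding; a mismatch beyond 1% of the frame grid is an error.
#' @param n_bins Number of bins (default `max(indices)`).
#' @return An object of class `"transition_counts"`: list with `lags_ns`,
#'   `lag_frames`, `mats` (one n_bins x n_bins matrix per lag, column =
#'   origin bin), `n_bins`, `dt_out`.
#' @export
count_transitions <- function(indices, dt_out, lags = c(5, 10, 20),
                              n_bins = max(indices)) {
  lag_frames <- round(lags / dt_out)
  stop_if(any(lag_frames < 1), "lag shorter than one frame")
  stop_if(any(abs(lag_frames * dt_out - lags) > 0.01 * lags),
          "lag is not a multiple of the frame spacing (mismatch > 1%)")
  n <- length(indices)
  stop_if(any(lag_frames >= n), "lag longer than trajectory")
  mats <- lapply(lag_frames, function(lf) {
    from <- indices[1:(n - lf)]
    to <- indices[(1 + lf):n]
    matrix(tabulate((from - 1L) * n_bins + to, n_bins * n_bins),
           nrow = n_bins)
  })
  structure(list(lags_ns = lags, lag_frames = lag_frames, mats = mats,
                 n_bins = as.integer(n_bins), dt_out = dt_out),
            class = "transition_counts")
}

#' Discretized diffusion landscape
#'
#' Per-bin free energies (kT) and per-interface diffusivities (nm^2/ns) on a
#' bin grid; the parametric object of the 1D diffusion model.
#'
#' @param F Free energies, one per bin (kT; any gauge).
#' @param D Diffusivities: either one value per interior interface
#'   (`n_bins - 1` values) or a single constant.
#' @param grid A `"bin_grid"` (see [discretize()]).
#' @return An object of class `"diffusion_landscape"`.
#' @export
diffusion_landscape <- function(F, D, grid) {
  nb <- grid$n_bins
  stop_if(length(F) != nb, "F must have one value per bin")
  stop_if(!(length(D) %in% c(1L, nb - 1L)),
          "D must be a constant or one value per interface")
  stop_if(any(D <= 0), "D must be positive")
  stop_if(any(!is.finite(F)), "F must be finite")
  structure(list(F = as.numeric(F), D = as.numeric(D), grid = grid),
            class = "diffusion_landscape")
}

#' @export
print.diffusion_landscape <- function(x, ...) {
  cat(sprintf(
    "<diffusion_landscape> %d bins over [%.3f, %.3f] nm; D %s nm^2/ns; F range %.2f kT\n",
    x$grid$n_bins, x$grid$edges[1], tail(x$grid$edges, 1),
    if (length(x$D) == 1) sprintf("= %.4g", x$D)
    else sprintf("in [%.3g, %.3g]", min(x$D), max(x$D)),
    diff(range(x$F))))
  invisible(x)
}

#' @export
plot.diffusion_landscape <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1)); on.exit(par(op))
  plot(x$grid$centers, x$F - min(x$F), type = "b", xlab = "r (nm)",
       ylab = "F (kT)", ...)
  Dv <- if (length(x$D) == 1) rep(x$D, x$grid$n_bins - 1) else x$D
  plot((x$grid$centers[-1] + x$grid$centers[-x$grid$n_bins]) / 2, Dv,
       type = "b", xlab = "r (nm)", ylab = "D (nm^2/ns)", ...)
  invisible(x)
}

#' Nearest-neighbour rate matrix of a diffusion landscape
#'
#' Maps the discretized landscape to the generator K of a birth-death master
#' equation dP/dt = K P with hopping rates
#' K\[i+-1, i\] = (D_interface / h^2) exp(-(F_neighbour - F_i)/2) and
#' diagonal entries set for zero column sums. Detailed balance with the
#' Boltzmann populations p_eq proportional to exp(-F) holds exactly by
#' construction. The spectral decomposition is computed through the
#' symmetrized matrix S = P_eq^(-1/2) K P_eq^(1/2) (orthonormal eigenvectors
#' phi_n), which fixes the eigenvector normalization used by
#' [correlation_function()].
#'
#' @param model A [diffusion_landscape()].
#' @return An object of class `"rate_matrix"`: `K`, `p_eq`, eigenvalues
#'   `lambda` (decreasing, lambda\[1\] = 0), `phi` (orthonormal eigenvectors
#'   of S), `sqrt_p`, and the grid.
#' @export
build_rate_matrix <- function(model) {
  stopifnot(inherits(model, "diffusion_landscape"))
  nb <- model$grid$n_bins
  h <- model$grid$h
  F <- model$F
  Dif <- if (length(model$D) == 1) rep(model$D, nb - 1) else model$D
  K <- matrix(0, nb, nb)
  up <- (Dif / h^2) * exp(-(F[-1] - F[-nb]) / 2)   # i -> i+1
  dn <- (Dif / h^2) * exp(-(F[-nb] - F[-1]) / 2)   # i+1 -> i
  K[cbind(2:nb, 1:(nb - 1))] <- up
  K[cbind(1:(nb - 1), 2:nb)] <- dn
  diag(K) <- -colSums(K)
  p <- exp(-(F - min(F)))
  p <- p / sum(p)
  sp <- sqrt(p)
  S <- K * outer(1 / sp, sp)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  structure(list(K = K, p_eq = p, lambda = es$values, phi = es$vectors,
                 sqrt_p = sp, grid = model$grid), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf(
    "<rate_matrix> %d bins; slowest relaxation time %.4g ns\n",
    length(x$p_eq), -1 / x$lambda[2]))
  invisible(x)
}

#' Propagator of a rate matrix
#'
#' exp(lag * K), a stochastic matrix (columns sum to 1) whose (j, i) entry
#' is the probability of bin j a time `lag` after bin i.
#'
#' @param rm A `"rate_matrix"`.
#' @param lag Lag time (ns).
#' @return The propagator matrix.
#' @export
propagator <- function(rm, lag) {
  ph <- rm$phi
  M <- ph %*% (exp(rm$lambda * lag) * t(ph))
  P <- M * outer(rm$sqrt_p, 1 / rm$sqrt_p)
  P[P < 0] <- 0
  P
}

#' Transition-count log-likelihood of a diffusion model
#'
#' ln L = sum over lags and bin pairs of N_ji(lag) ln p(j, t + lag | i, t),
#' with propagator entries floored at 1e-300 before the logarithm.
#'
#' @param counts A `"transition_counts"`.
#' @param rm A `"rate_matrix"` on the same grid.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(counts, rm) {
  stop_if(counts$n_bins != length(rm$p_eq),
          "counts and rate matrix have different bin counts")
  ll <- 0
  for (k in seq_along(counts$mats)) {
    P <- propagator(rm, counts$lags_ns[k])
    N <- counts$mats[[k]]
    nz <- N > 0
    ll <- ll + sum(N[nz] * log(pmax(P[nz], 1e-300)))
  }
  ll
}

#' Fit a diffusion landscape to transition counts
#'
#' Metropolis random walk over per-bin free energies (gauge: the most
#' occupied bin is fixed at F = 0) and log-diffusivities, with flat priors,
#' targeting the transition-count likelihood. Proposals perturb one random
#' coordinate per step (Gaussian, sd `sigma_F` on F and `sigma_lnD` on
#' ln D); 20% of steps shift all log-diffusivities jointly to decorrelate
#' the overall time scale. In `constant_D` mode all interfaces share one
#' diffusivity. Returns both the maximum-likelihood and the posterior-mean
#' parameters (second half of the chain).
#'
#' @param counts A `"transition_counts"` (two or more lags recommended).
#' @param grid The `"bin_grid"` the counts were taken on.
#' @param mode `"position_dependent"` or `"constant_D"`.
#' @param n_steps Number of Metropolis steps.
#' @param seed Integer seed.
#' @param sigma_F,sigma_lnD Proposal widths.
#' @param F_max Cap (kT) on free energies of empty bins (keeps the generator
#'   irreducible).
#' @param init Optional [diffusion_landscape()] to start from; default is
#'   F from occupancy (-log counts) and D from the short-lag mean-square
#'   displacement.
#' @return An object of class `"landscape_fit"`: `ml` and `posterior_mean`
#'   landscapes, `logL`, `acceptance`, `trace` (thinned lnL), and the inputs'
#'   metadata.
#' @export
fit_landscape <- function(counts, grid, mode = c("position_dependent",
                                                 "constant_D"),
                          n_steps = 20000, seed = NULL, sigma_F = 0.2,
                          sigma_lnD = 0.1, F_max = 20, init = NULL) {
  mode <- match.arg(mode)
  nb <- counts$n_bins
  stop_if(sum(sapply(counts$mats, sum)) == 0, "no usable transitions")
  occ <- rowSums(counts$mats[[1]]) + colSums(counts$mats[[1]])
  anchor <- which.max(occ)
  if (is.null(init)) {
    Fi <- -log(pmax(occ / sum(occ), 1e-12))
    Fi <- pmin(Fi - Fi[anchor], F_max)
    # crude D: mean-square bin displacement at the shortest lag
    k <- which.min(counts$lag_frames)
    N <- counts$mats[[k]]
    disp2 <- sum(N * outer(grid$centers, grid$centers,
                           function(a, b) (a - b)^2)) / sum(N)
    D0 <- max(disp2 / (2 * counts$lags_ns[k]), 1e-6)
    lnD <- rep(log(D0), if (mode == "constant_D") 1 else nb - 1)
  } else {
    Fi <- pmin(init$F - init$F[anchor], F_max)
    lnD <- log(if (mode == "constant_D") init$D[1]
               else rep(init$D, length.out = nb - 1))
  }
  make_rm <- function(Fv, lnDv) {
    build_rate_matrix(diffusion_landscape(Fv, exp(lnDv), grid))
  }
  cur_ll <- log_likelihood(counts, make_rm(Fi, lnD))
  best <- list(F = Fi, lnD = lnD, ll = cur_ll)
  nF <- nb - 1 # free F coordinates (anchor fixed)
  free_bins <- setdiff(seq_len(nb), anchor)
  acc <- 0
  half <- n_steps %/% 2
  sumF <- numeric(nb); sumlnD <- numeric(length(lnD)); n_post <- 0
  trace <- numeric(0)
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      Fp <- Fi; lnDp <- lnD
      u <- runif(1)
      if (u < 0.2) {
        lnDp <- lnD + rnorm(1, sd = sigma_lnD) # global D shift
      } else {
        j <- sample.int(nF + length(lnD), 1)
        if (j <= nF) {
          b <- free_bins[j]
          Fp[b] <- Fi[b] + rnorm(1, sd = sigma_F)
          if (Fp[b] > F_max) Fp[b] <- F_max
        } else {
          jj <- j - nF
          lnDp[jj] <- lnD[jj] + rnorm(1, sd = sigma_lnD)
        }
      }
      ll_p <- log_likelihood(counts, make_rm(Fp, lnDp))
      if (is.finite(ll_p) && log(runif(1)) < ll_p - cur_ll) {
        Fi <- Fp; lnD <- lnDp; cur_ll <- ll_p; acc <- acc + 1
        if (cur_ll > best$ll) best <- list(F = Fi, lnD = lnD, ll = cur_ll)
      }
      if (s > half) {
        sumF <- sumF + Fi; sumlnD <- sumlnD + lnD; n_post <- n_post + 1
      }
      if (s %% 200 == 0) trace <- c(trace, cur_ll)
    }
  })
  if (acc / n_steps < 0.01) {
    warning(sprintf("Metropolis acceptance rate %.2f%%: chain may not mix",
                    100 * acc / n_steps))
  }
  ml <- diffusion_landscape(best$F, exp(best$lnD), grid)
  pm <- diffusion_landscape(sumF / n_post, exp(sumlnD / n_post), grid)
  structure(list(ml = ml, posterior_mean = pm, logL = best$ll,
                 acceptance = acc / n_steps, trace = trace, mode = mode,
                 n_steps = n_steps, seed = seed),
            class = "landscape_fit")
}

#' @export
print.landscape_fit <- function(x, ...) {
  cat(sprintf(
    "<landscape_fit> mode %s, %d Metropolis steps, acceptance %.1f%%, max lnL = %.2f\n",
    x$mode, x$n_steps, 100 * x$acceptance, x$logL))
  cat("  ML landscape: "); print(x$ml)
  invisible(x)
}

# Spectral weights of the distance autocorrelation: w_n = (sum_i r_i
# sqrt(p_i) phi_n,i)^2 for the non-stationary modes. With the symmetrized
# eigenvectors this equals the exact autocorrelation decomposition of the
# Markov chain.
corr_weights <- function(rm, centers) {
  proj <- as.vector((centers * rm$sqrt_p) %*% rm$phi)
  w <- proj^2
  w[1] <- 0 # stationary mode carries the mean
  w
}

#' Distance autocorrelation function of a rate matrix
#'
#' C(t) = sum_n>=2 w_n exp(lambda_n t) / sum_n>=2 w_n, with spectral weights
#' w_n = (r . sqrt(p_eq) phi_n)^2 chosen so that C(t) is the exact
#' normalized autocorrelation <dr(0) dr(t)> / Var\[r\] of the stationary
#' Markov chain; C(0) = 1.
#'
#' @param rm A `"rate_matrix"`.
#' @param centers Bin centers (nm); default from the grid.
#' @param t Time grid (ns); default spans five times the slowest relaxation.
#' @return List with `t` and `C`.
#' @export
correlation_function <- function(rm, centers = rm$grid$centers, t = NULL) {
  w <- corr_weights(rm, centers)
  stop_if(sum(w) <= 0, "degenerate: distance constant over the stationary law")
  if (is.null(t)) t <- seq(0, -5 / rm$lambda[2], length.out = 200)
  C <- sapply(t, function(tt) sum(w * exp(rm$lambda * tt))) / sum(w)
  list(t = t, C = C)
}

#' Distance correlation time of a rate matrix
#'
#' tau = sum_n>=2 w_n / |lambda_n| / sum_n>=2 w_n, the time integral of the
#' normalized autocorrelation function.
#'
#' @inheritParams correlation_function
#' @return Correlation time (ns).
#' @export
correlation_time <- function(rm, centers = rm$grid$centers) {
  w <- corr_weights(rm, centers)
  stop_if(sum(w) <= 0, "degenerate: distance constant over the stationary law")
  lam <- rm$lambda
  sum(w[-1] / abs(lam[-1])) / sum(w[-1])
}
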