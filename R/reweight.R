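#' Weighted conformational ensemble
#'
#' Frames with per-frame transfer efficiency, salt-bridge counts by type and
#' normalized statistical weights: the substrate of all reweighting
#' operations.
#'
#' @param E Per-frame transfer efficiencies.
#' @param counts Matrix (n_frames x 4) of non-negative integer salt-bridge
#'   counts with columns `EK`, `ER`, `DK`, `DR` (Glu-Lys, Glu-Arg, Asp-Lys,
#'   Asp-Arg).
#' @param weights Frame weights; normalized to sum 1 (validated to 1e-10
#'   after normalization). Default uniform.
#' @param label Ensemble label.
#' @return An object of class `"weighted_ensemble"`.
#' @export
weighted_ensemble <- function(E, counts, weights = NULL, label = "") {
  n <- length(E)
  counts <- as.matrix(counts)
  stop_if(nrow(counts) != n, "counts and E must have the same number of frames")
  stop_if(ncol(counts) != 4, "counts must have 4 columns (EK, ER, DK, DR)")
  stop_if(any(counts < 0) || any(counts != round(counts)),
          "counts must be non-negative integers")
  colnames(counts) <- c("EK", "ER", "DK", "DR")
  if (is.null(weights)) weights <- rep(1 / n, n)
  stop_if(length(weights) != n, "weights and E must have equal length")
  stop_if(any(weights < 0), "weights must be non-negative")
  s <- sum(weights)
  stop_if(abs(s - 1) > 1e-6 && abs(s) < 1e-300, "weights must have positive sum")
  weights <- weights / s
  structure(list(E = as.numeric(E), counts = counts, weights = weights,
                 label = label), class = "weighted_ensemble")
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat(sprintf(
    "<weighted_ensemble> %s: %d frames, <E> = %.3f, mean counts EK/ER/DK/DR = %s, ESS = %.0f\n",
    if (nzchar(x$label)) x$label else "(unlabelled)", length(x$E),
    sum(x$weights * x$E),
    paste(sprintf("%.2f", colSums(x$counts * x$weights)), collapse = "/"),
    effective_sample_size(x$weights)))
  invisible(x)
}

#' Salt-bridge energy perturbation parameters
#'
#' Either a single uniform correction `eps_sb` applied to every salt bridge,
#' or four type-specific corrections (all in kT). Positive values weaken the
#' force-field salt bridges on reweighting.
#'
#' @param eps_EK,eps_ER,eps_DK,eps_DR Type-specific energies (kT).
#' @param eps_sb Uniform energy (kT); if given, overrides the four types.
#' @return An object of class `"salt_bridge_params"` with fields `eps`
#'   (named length-4 vector) and `uniform` (logical).
#' @export
salt_bridge_params <- function(eps_EK = 0, eps_ER = 0, eps_DK = 0,
                               eps_DR = 0, eps_sb = NULL) {
  if (!is.null(eps_sb)) {
    stop_if(!is.finite(eps_sb), "eps_sb must be finite")
    eps <- rep(eps_sb, 4)
    uniform <- TRUE
  } else {
    eps <- c(eps_EK, eps_ER, eps_DK, eps_DR)
    stop_if(any(!is.finite(eps)), "energies must be finite")
    uniform <- FALSE
  }
  structure(list(eps = setNames(eps, c("EK", "ER", "DK", "DR")),
                 uniform = uniform), class = "salt_bridge_params")
}

#' @export
print.salt_bridge_params <- function(x, ...) {
  if (x$uniform) {
    cat(sprintf("<salt_bridge_params> uniform eps_sb = %.3f kT\n", x$eps[1]))
  } else {
    cat(sprintf(
      "<salt_bridge_params> eps_EK = %.3f, eps_ER = %.3f, eps_DK = %.3f, eps_DR = %.3f kT\n",
      x$eps[1], x$eps[2], x$eps[3], x$eps[4]))
  }
  invisible(x)
}

#' Count possible salt bridges in a sequence
#'
#' Number of oppositely charged residue pairs (one of Asp/Glu with one of
#' Lys/Arg) separated by at least three residues along the sequence.
#'
#' @param sequence One-letter amino-acid string.
#' @return Integer pair count.
#' @examples
#' possible_salt_bridges("KAAE") # 1
#' possible_salt_bridges("KAE")  # 0: separation 2 < 3
#' @export
possible_salt_bridges <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  stop_if(!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
          "unknown amino-acid letters in sequence")
  neg <- which(aa %in% c("D", "E"))
  pos <- which(aa %in% c("K", "R"))
  if (length(neg) == 0 || length(pos) == 0) return(0L)
  sum(abs(outer(neg, pos, "-")) >= 3)
}

#' Hysteretic contact-state assignment
#'
#' Two-threshold (core/transition) contact automaton: starting from the
#' unformed state, a contact forms when the minimum heavy-atom distance drops
#' below `form_cut` and, once formed, persists until the distance exceeds
#' `break_cut`.
#'
#' @param distance_series Per-frame minimum heavy-atom distances (nm).
#' @param form_cut Formation threshold (nm, default 0.38).
#' @param break_cut Breaking threshold (nm, default 0.8); must exceed
#'   `form_cut`.
#' @return Integer vector of 0/1 contact states.
#' @examples
#' contact_states(c(0.50, 0.36, 0.60, 0.79, 0.85, 0.37))
#' @export
contact_states <- function(distance_series, form_cut = 0.38, break_cut = 0.8) {
  stop_if(form_cut >= break_cut, "form_cut must be smaller than break_cut")
  below <- distance_series < form_cut
  above <- distance_series > break_cut
  state <- integer(length(distance_series))
  s <- 0L
  for (i in seq_along(distance_series)) {
    if (s == 0L && below[i]) s <- 1L
    else if (s == 1L && above[i]) s <- 0L
    state[i] <- s
  }
  state
}

#' Boltzmann reweighting by salt-bridge counts
#'
#' New frame weights w_i proportional to w0_i exp(-sum_AB N_AB(i) eps_AB),
#' renormalized; the exponent is max-shifted to avoid overflow.
#'
#' @param ens A [weighted_ensemble()].
#' @param params A [salt_bridge_params()].
#' @return Normalized weight vector.
#' @export
reweight_weights <- function(ens, params) {
  stopifnot(inherits(ens, "weighted_ensemble"),
            inherits(params, "salt_bridge_params"))
  expo <- -as.vector(ens$counts %*% params$eps)
  expo <- expo - max(expo)
  w <- ens$weights * exp(expo)
  w / sum(w)
}

#' Effective sample size of a weight vector
#'
#' Kish effective sample size 1 / sum(w_i^2) of normalized weights.
#'
#' @param w Normalized weights.
#' @return Effective number of frames, in \[1, length(w)\].
#' @export
effective_sample_size <- function(w) 1 / sum((w / sum(w))^2)

#' Chi-square misfit and analytical gradient of salt-bridge reweighting
#'
#' Data term chi^2 = sum_p ((<E>_rw,p - E_expt,p)/sigma)^2 over proteins,
#' with the analytical gradient with respect to each energy component
#' d chi^2 / d eps_AB = (2/sigma^2) (<E>_rw - E_expt)
#' (<E>_rw <n_AB>_rw - <E n_AB>_rw), summed over proteins. `sigma = NULL`
#' gives the unweighted form (no sigma^2 divisor).
#'
#' @param ensembles List of [weighted_ensemble()].
#' @param E_expt Experimental mean efficiencies, aligned with `ensembles`.
#' @param params A [salt_bridge_params()].
#' @param sigma Experimental uncertainty of each mean efficiency (single
#'   value or per-protein); `NULL` for the unweighted chi^2.
#' @return List with `chi2`, `grad` (length 4, kT^-1) and `E_rw`.
#' @export
chi2_and_grad <- function(ensembles, E_expt, params, sigma = NULL) {
  stop_if(length(ensembles) != length(E_expt),
          "ensembles and E_expt must be aligned")
  s2 <- if (is.null(sigma)) rep(1, length(E_expt))
        else rep(sigma, length.out = length(E_expt))^2
  chi2 <- 0
  grad <- numeric(4)
  E_rw <- numeric(length(ensembles))
  for (p in seq_along(ensembles)) {
    e <- ensembles[[p]]
    w <- reweight_weights(e, params)
    Ew <- sum(w * e$E)
    E_rw[p] <- Ew
    d <- Ew - E_expt[p]
    chi2 <- chi2 + d^2 / s2[p]
    nbar <- colSums(w * e$counts)
    Enbar <- colSums(w * e$E * e$counts)
    grad <- grad + 2 * d * (Ew * nbar - Enbar) / s2[p]
  }
  list(chi2 = chi2, grad = setNames(grad, c("EK", "ER", "DK", "DR")),
       E_rw = E_rw)
}

#' Scan a uniform salt-bridge correction
#'
#' Evaluates the chi-square misfit of reweighted mean efficiencies against
#' experimental values on a grid of uniform perturbation strengths and
#' returns the minimizing value with the full curve.
#'
#' @inheritParams chi2_and_grad
#' @param grid Energies to scan (kT).
#' @return An object of class `"reweight_scan"`: list with `eps_opt`,
#'   `chi2_min`, `grid`, `chi2`, per-protein reweighted means at the optimum
#'   and effective sample sizes.
#' @export
scan_uniform <- function(ensembles, E_expt, grid = seq(0, 2, by = 0.05),
                         sigma = NULL) {
  stop_if(length(grid) == 0, "grid must be non-empty")
  chi2 <- vapply(grid, function(eps) {
    chi2_and_grad(ensembles, E_expt,
                  salt_bridge_params(eps_sb = eps), sigma)$chi2
  }, numeric(1))
  i <- which.min(chi2)
  opt <- salt_bridge_params(eps_sb = grid[i])
  at_opt <- chi2_and_grad(ensembles, E_expt, opt, sigma)
  ess <- vapply(ensembles, function(e)
    effective_sample_size(reweight_weights(e, opt)), numeric(1))
  structure(list(eps_opt = grid[i], chi2_min = chi2[i], grid = grid,
                 chi2 = chi2, E_rw = at_opt$E_rw, ess = ess),
            class = "reweight_scan")
}

#' @export
print.reweight_scan <- function(x, ...) {
  cat(sprintf(
    "<reweight_scan> optimal uniform eps_sb = %.3f kT (chi2 = %.4g) over [%g, %g]\n",
    x$eps_opt, x$chi2_min, min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
plot.reweight_scan <- function(x, ...) {
  plot(x$grid, x$chi2, type = "b", xlab = "eps_sb (kT)",
       ylab = expression(chi^2), ...)
  abline(v = x$eps_opt, lty = 2)
  invisible(x)
}

#' Four-parameter salt-bridge correction by regularized gradient descent
#'
#' Minimizes L = chi^2 + (gamma/2) (eps_EK + eps_ER + eps_DK + eps_DR)^2
#' with the analytical chi-square gradient and an adaptive step size (step
#' grows by 1.2 after a decrease of L, shrinks by 0.5 after an increase,
#' whose trial move is rejected). Converged when |delta L| < `tol`.
#'
#' @inheritParams chi2_and_grad
#' @param gamma Regularization constant (default 1.0) penalizing large total
#'   contact energies.
#' @param sigma Experimental uncertainty on each mean efficiency; default
#'   0.03, matching the experimental transfer-efficiency uncertainty.
#'   `NULL` gives the unweighted chi^2 (then gamma should be scaled down
#'   accordingly, since the data term is ~1e4 times smaller).
#' @param start Starting energies (kT).
#' @param step0 Initial step size.
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on |delta L|.
#' @return An object of class `"reweight_fit"`: optimal
#'   [salt_bridge_params()], `chi2`, `L`, per-protein reweighted means,
#'   effective sample sizes, convergence flag and iteration trace.
#' @export
fit_four_param <- function(ensembles, E_expt, gamma = 1.0, sigma = 0.03,
                           start = c(0, 0, 0, 0), step0 = 0.01,
                           max_iter = 5000, tol = 1e-10) {
  eps <- setNames(as.numeric(start), c("EK", "ER", "DK", "DR"))
  objective <- function(eps) {
    cg <- chi2_and_grad(ensembles, E_expt,
                        salt_bridge_params(eps[1], eps[2], eps[3], eps[4]),
                        sigma)
    list(L = cg$chi2 + 0.5 * gamma * sum(eps)^2,
         grad = cg$grad + gamma * sum(eps), chi2 = cg$chi2)
  }
  cur <- objective(eps)
  step <- step0
  trace <- matrix(NA_real_, nrow = 0, ncol = 6,
                  dimnames = list(NULL, c("EK", "ER", "DK", "DR", "L", "step")))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    trial <- eps - step * cur$grad
    new <- objective(trial)
    if (new$L <= cur$L) {
      if (abs(cur$L - new$L) < tol) {
        eps <- trial; cur <- new; converged <- TRUE
        trace <- rbind(trace, c(eps, cur$L, step))
        break
      }
      eps <- trial; cur <- new; step <- step * 1.2
    } else {
      step <- step * 0.5
      if (step < 1e-14) { converged <- TRUE; break }
    }
    if (it %% 25 == 0) trace <- rbind(trace, c(eps, cur$L, step))
  }
  opt <- salt_bridge_params(eps[1], eps[2], eps[3], eps[4])
  ess <- vapply(ensembles, function(e)
    effective_sample_size(reweight_weights(e, opt)), numeric(1))
  E_rw <- chi2_and_grad(ensembles, E_expt, opt, sigma)$E_rw
  structure(list(params = opt, chi2 = cur$chi2, L = cur$L, E_rw = E_rw,
                 ess = ess, converged = converged, gamma = gamma,
                 sigma = sigma, trace = trace),
            class = "reweight_fit")
}

#' @export
print.reweight_fit <- function(x, ...) {
  cat("<reweight_fit> four-parameter salt-bridge correction\n  ")
  print(x$params)
  cat(sprintf("  chi2 = %.4g, L = %.4g, converged: %s\n",
              x$chi2, x$L, x$converged))
  invisible(x)
}

#' Bayesian (maximum-entropy) ensemble reweighting
#'
#' Minimizes theta * KL(w || w0) + chi^2(w)/2 over the weight simplex, where
#' chi^2 is built from the reweighted mean efficiency and the reweighted
#' variance of the efficiency distribution against experimental targets with
#' stated uncertainties. The stationary weights have the exponential-family
#' form w_i proportional to w0_i exp(-(l1 E_i + l2 E_i^2)/theta), so the
#' problem is solved in the two-dimensional dual space of (l1, l2).
#'
#' @param ens A [weighted_ensemble()] (>= 10 frames).
#' @param target_E Target mean transfer efficiency.
#' @param target_varE Target variance of the transfer-efficiency
#'   distribution.
#' @param sigma_E,sigma_varE Uncertainties of the two targets (defaults 0.03
#'   and 0.02, the experimental uncertainties).
#' @param theta Confidence parameter balancing prior ensemble against data
#'   (default 10); smaller theta enforces the targets more strictly.
#' @return An object of class `"bioen_fit"`: `weights`, `kl`, achieved
#'   `E`, `varE`, per-observable standardized residuals, `theta`, and an
#'   `infeasible` flag set when a target lies outside the convex hull of the
#'   frame observables.
#' @export
bioen_fit <- function(ens, target_E, target_varE, sigma_E = 0.03,
                      sigma_varE = 0.02, theta = 10) {
  stopifnot(inherits(ens, "weighted_ensemble"))
  stop_if(length(ens$E) < 10, "need at least 10 frames")
  E <- ens$E; w0 <- ens$weights
  infeasible <- target_E < min(E) || target_E > max(E) || target_varE < 0
  wts <- function(l) {
    expo <- -(l[1] * E + l[2] * E^2) / theta
    expo <- expo - max(expo)
    w <- w0 * exp(expo)
    w / sum(w)
  }
  obj <- function(l) {
    w <- wts(l)
    m1 <- sum(w * E); m2 <- sum(w * E^2)
    v <- m2 - m1^2
    kl <- sum(w * log(pmax(w, 1e-300) / pmax(w0, 1e-300)))
    chi2 <- ((m1 - target_E) / sigma_E)^2 + ((v - target_varE) / sigma_varE)^2
    theta * kl + chi2 / 2
  }
  fit <- optim(c(0, 0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  # polish: the dual objective is stiff for small theta
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-15))
  w <- wts(fit$par)
  m1 <- sum(w * E); v <- sum(w * E^2) - m1^2
  structure(list(weights = w,
                 kl = sum(w * log(pmax(w, 1e-300) / pmax(w0, 1e-300))),
                 E = m1, varE = v,
                 residuals = c(E = (m1 - target_E) / sigma_E,
                               varE = (v - target_varE) / sigma_varE),
                 theta = theta, infeasible = infeasible,
                 ess = effective_sample_size(w)),
            class = "bioen_fit")
}

#' @export
print.bioen_fit <- function(x, ...) {
  cat(sprintf(
    "<bioen_fit> theta = %g: <E> = %.4f, Var[E] = %.4f, KL = %.4g, ESS = %.0f%s\n",
    x$theta, x$E, x$varE, x$kl, x$ess,
    if (x$infeasible) " [targets infeasible]" else ""))
  invisible(x)
}
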