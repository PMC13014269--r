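#' Monte-Carlo correlation coefficient with measurement errors
#'
#' Propagates per-point uncertainties into a correlation estimate by
#' generating `n_sets` synthetic data sets, resampling every point from
#' Normal(mean, error), computing the Pearson correlation of each set and
#' returning the mean and standard deviation over sets. With zero errors
#' every set is identical and the plain Pearson correlation is returned with
#' sd 0.
#'
#' @param x,y Point estimates (aligned, n >= 3).
#' @param x_err,y_err Standard errors (scalars or vectors; default 0).
#' @param n_sets Number of synthetic data sets (default 100).
#' @param seed Integer seed.
#' @return List with `rho_mc`, `sd` and the per-set correlations `rho_sets`.
#' @export
rho_mc <- function(x, y, x_err = 0, y_err = 0, n_sets = 100, seed = NULL) {
  n <- length(x)
  stop_if(n < 3, "need at least 3 points")
  stop_if(length(y) != n, "x and y must be aligned")
  x_err <- rep(x_err, length.out = n)
  y_err <- rep(y_err, length.out = n)
  rhos <- with_seed(seed, vapply(seq_len(n_sets), function(s) {
    cor(x + rnorm(n, 0, x_err), y + rnorm(n, 0, y_err))
  }, numeric(1)))
  list(rho_mc = mean(rhos), sd = sd(rhos), rho_sets = rhos)
}

#' Lin's concordance correlation coefficient
#'
#' rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2), measuring
#' agreement with the identity line (population 1/n moments); equals 1 only
#' for y = x.
#'
#' @param x,y Paired values (n >= 2).
#' @return Concordance coefficient in \[-1, 1\].
#' @export
lin_ccc <- function(x, y) {
  n <- length(x)
  stop_if(n < 2 || length(y) != n, "need aligned vectors of length >= 2")
  mx <- mean(x); my <- mean(y)
  sx <- mean((x - mx)^2); sy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  stop_if(sx == 0 && sy == 0, "zero variance in both inputs")
  2 * sxy / (sx + sy + (mx - my)^2)
}

# Kyte-Doolittle hydropathy, rescaled to [0, 1].
kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

charge_of <- function(aa) {
  q <- integer(length(aa))
  q[aa %in% c("D", "E")] <- -1L
  q[aa %in% c("K", "R")] <- 1L
  q
}

# Charge-patterning delta for one blob size: mean squared deviation of the
# blob charge asymmetry sigma = (f+ - f-)^2 / (f+ + f-) from the global one.
kappa_delta <- function(q, g) {
  n <- length(q)
  if (n < g) return(NA_real_)
  fp <- mean(q == 1); fm <- mean(q == -1)
  sig_glob <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  nb <- n - g + 1
  cp <- c(0, cumsum(q == 1)); cm <- c(0, cumsum(q == -1))
  bp <- (cp[(g + 1):(n + 1)] - cp[1:nb]) / g
  bm <- (cm[(g + 1):(n + 1)] - cm[1:nb]) / g
  sig <- ifelse(bp + bm > 0, (bp - bm)^2 / (bp + bm), 0)
  mean((sig - sig_glob)^2)
}

# Normalization: the maximum delta attainable by rearranging the same
# composition, searched over the fully segregated arrangement plus a
# deterministic set of random shuffles.
kappa_delta_max <- function(q, g, n_shuffle = 200) {
  seg <- sort(q) # fully segregated: all -1, then 0, then +1
  dmax <- kappa_delta(seg, g)
  shuffles <- with_seed(1L, replicate(n_shuffle, sample(q)))
  dmax <- max(dmax, apply(shuffles, 2, kappa_delta, g = g))
  dmax
}

#' Sequence descriptors of a disordered region
#'
#' Computes the standard charge/hydropathy descriptors used to characterize
#' IDR sequences: net charge per residue (NCPR), fraction of charged
#' residues (FCR), mean hydrophobicity (Kyte-Doolittle rescaled to
#' \[0, 1\]), number of possible salt bridges (see
#' [possible_salt_bridges()]), the kappa charge-patterning parameter (blob
#' sizes 5 and 6 averaged, normalized by the maximal-asymmetry arrangement
#' of the same composition) and the sequence charge decoration
#' SCD = (1/N) sum_(i<j) q_i q_j sqrt(j - i).
#'
#' @param sequence One-letter amino-acid string (D/E negative, K/R positive,
#'   histidine neutral, termini uncharged).
#' @return An object of class `"sequence_properties"` (named list).
#' @examples
#' sequence_properties("EKEKEKEKEK")
#' @export
sequence_properties <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  stop_if(!all(aa %in% names(kd_scale)), "unknown amino-acid letters")
  q <- charge_of(aa)
  n <- length(aa)
  ncpr <- sum(q) / n
  fcr <- mean(q != 0)
  hyd <- mean((kd_scale[aa] + 4.5) / 9)
  idx <- which(q != 0)
  scd <- if (length(idx) >= 2) {
    pr <- t(utils::combn(idx, 2))
    sum(q[pr[, 1]] * q[pr[, 2]] * sqrt(pr[, 2] - pr[, 1])) / n
  } else 0
  kap <- if (sum(q == 1) > 0 && sum(q == -1) > 0) {
    ks <- vapply(c(5, 6), function(g) {
      dm <- kappa_delta_max(q, g)
      if (is.na(dm) || dm == 0) NA_real_ else kappa_delta(q, g) / dm
    }, numeric(1))
    mean(ks, na.rm = TRUE)
  } else NA_real_
  structure(list(NCPR = ncpr, FCR = fcr, hydrophobicity = unname(hyd),
                 n_possible_salt_bridges = possible_salt_bridges(sequence),
                 kappa = kap, SCD = scd), class = "sequence_properties")
}

#' @export
print.sequence_properties <- function(x, ...) {
  cat(sprintf(
    "<sequence_properties> NCPR = %+.3f, FCR = %.3f, hyd = %.3f, pairs = %d, kappa = %s, SCD = %+.3f\n",
    x$NCPR, x$FCR, x$hydrophobicity, x$n_possible_salt_bridges,
    if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa), x$SCD))
  invisible(x)
}

#' Variance/diffusivity decomposition of reconfiguration times
#'
#' The "dynamical buffering" thought experiment: correlation times
#' tau = Var\[r\]/D are recomputed under three scenarios -- (i) the
#' diffusion coefficient fixed to its cross-protein mean, (ii) the distance
#' variance fixed to its cross-protein mean, (iii) both varying as observed
#' -- and each tau set is correlated (Monte-Carlo Pearson, [rho_mc()])
#' against the mean transfer efficiencies. Compensation between narrowing
#' distributions and decreasing diffusivity shows up as a much weaker
#' scenario (iii) correlation than either single-variable scenario.
#'
#' @param summaries Data frame with columns `label`, `mean_E`, `var_r`
#'   (nm^2), `D_const` (nm^2/ns) and optionally `mean_E_err`, `var_r_err`,
#'   `D_err`.
#' @param n_sets,seed Passed to [rho_mc()].
#' @return An object of class `"buffering_decomposition"`: the augmented
#'   table (`tau_fixed_D`, `tau_fixed_var`, `tau_full` in ns), the
#'   correlations with `mean_E` per scenario (with sd), and flags for
#'   degenerate (zero-variance) scenarios.
#' @export
buffering_decomposition <- function(summaries, n_sets = 100, seed = NULL) {
  need <- c("mean_E", "var_r", "D_const")
  stop_if(!all(need %in% names(summaries)), "missing required columns")
  s <- summaries
  stop_if(any(s$D_const <= 0), "D_const must be positive")
  Dbar <- mean(s$D_const)
  vbar <- mean(s$var_r)
  tab <- data.frame(label = if ("label" %in% names(s)) s$label
                            else seq_len(nrow(s)),
                    mean_E = s$mean_E,
                    tau_fixed_D = s$var_r / Dbar,
                    tau_fixed_var = vbar / s$D_const,
                    tau_full = s$var_r / s$D_const)
  e_err <- s$mean_E_err %||% 0
  res <- lapply(c("tau_fixed_D", "tau_fixed_var", "tau_full"), function(cn) {
    tv <- tab[[cn]]
    if (sd(tv) == 0 || sd(tab$mean_E) == 0) {
      list(rho_mc = NA_real_, sd = NA_real_, degenerate = TRUE)
    } else {
      r <- rho_mc(tab$mean_E, tv, x_err = e_err, n_sets = n_sets,
                  seed = seed)
      list(rho_mc = r$rho_mc, sd = r$sd, degenerate = FALSE)
    }
  })
  names(res) <- c("fixed_D", "fixed_var", "full")
  structure(list(table = tab, correlations = res),
            class = "buffering_decomposition")
}

#' @export
print.buffering_decomposition <- function(x, ...) {
  cat("<buffering_decomposition> rho_MC of tau with <E>:\n")
  for (nm in names(x$correlations)) {
    r <- x$correlations[[nm]]
    if (r$degenerate) cat(sprintf("  %-10s degenerate (zero variance)\n", nm))
    else cat(sprintf("  %-10s %+0.3f (%.3f)\n", nm, r$rho_mc, r$sd))
  }
  invisible(x)
}

#' Correlate simulation-experiment efficiency deviations with sequence
#' descriptors
#'
#' Pearson correlation of the per-protein deviation <E>_sim - <E>_exp
#' against each sequence descriptor; degenerate descriptors (zero variance,
#' or all-zero deviations) are flagged rather than returned as NaN.
#'
#' @param deltas Per-protein efficiency deviations (n >= 3).
#' @param props List of [sequence_properties()] (one per protein) or a data
#'   frame of descriptor columns.
#' @return Data frame with `descriptor`, `rho`, `flag`.
#' @export
deviation_correlations <- function(deltas, props) {
  stop_if(length(deltas) < 3, "need at least 3 proteins")
  df <- if (is.data.frame(props)) props
        else as.data.frame(do.call(rbind, lapply(props, function(p)
          unlist(p[c("NCPR", "FCR", "hydrophobicity",
                     "n_possible_salt_bridges", "kappa", "SCD")]))))
  stop_if(nrow(df) != length(deltas), "deltas and props must be aligned")
  out <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (sd(deltas) == 0 || any(is.na(v)) || sd(v) == 0) {
      data.frame(descriptor = nm, rho = NA_real_, flag = "degenerate")
    } else {
      data.frame(descriptor = nm, rho = cor(deltas, v), flag = "")
    }
  })
  do.call(rbind, out)
}
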