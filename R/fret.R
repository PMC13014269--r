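#' FRET configuration
#'
#' @param R0 Foerster radius (nm); default 6.0 (Cy3B/CF660R pair).
#' @param kD Donor excited-state decay rate (1/ns).
#' @param t_max Survival-probability integration horizon (ns); default 20,
#'   long enough that the survival has effectively decayed.
#' @param quench_cutoff Donor-acceptor contact distance (nm) below which the
#'   dyes are treated as nonemissive (default 0.4, van der Waals contact).
#' @return An object of class `"fret_config"`.
#' @export
fret_config <- function(R0 = 6.0, kD = 1 / 3.8, t_max = 20,
                        quench_cutoff = 0.4) {
  stop_if(R0 <= 0, "R0 must be positive")
  stop_if(kD <= 0, "kD must be positive")
  stop_if(t_max <= 0, "t_max must be positive")
  structure(list(R0 = R0, kD = kD, t_max = t_max,
                 quench_cutoff = quench_cutoff), class = "fret_config")
}

#' Dye trajectory container
#'
#' Per-frame donor/acceptor transition-dipole unit vectors, interdye vector
#' and minimum donor-acceptor heavy-atom distance, on a uniform time grid
#' (typically 0.02 ns frame spacing).
#'
#' @param dt_out Frame spacing (ns).
#' @param donor,acceptor n x 3 matrices of dipole unit vectors.
#' @param separation n x 3 matrix of interdye vectors (nm), non-zero norm.
#' @param min_DA n-vector of minimum donor-acceptor heavy-atom distances
#'   (nm); default Inf (never quenched).
#' @return An object of class `"dye_trajectory"`.
#' @export
dye_trajectory <- function(dt_out, donor, acceptor, separation,
                           min_DA = NULL) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  separation <- as.matrix(separation)
  n <- nrow(donor)
  stop_if(nrow(acceptor) != n || nrow(separation) != n,
          "donor, acceptor and separation must have equal frame counts")
  stop_if(dt_out <= 0, "dt_out must be positive")
  nrm <- function(m) sqrt(rowSums(m^2))
  stop_if(any(abs(nrm(donor) - 1) > 1e-6) || any(abs(nrm(acceptor) - 1) > 1e-6),
          "dipole vectors must be unit norm")
  r <- nrm(separation)
  stop_if(any(r == 0), "interdye vector norm must be positive")
  if (is.null(min_DA)) min_DA <- rep(Inf, n)
  structure(list(dt_out = dt_out, donor = donor, acceptor = acceptor,
                 separation = separation, r = r, min_DA = min_DA),
            class = "dye_trajectory")
}

#' Instantaneous orientational factor
#'
#' kappa^2 = (d_D . d_A - 3 (d_D . r_hat)(d_A . r_hat))^2, in \[0, 4\];
#' its isotropic average is 2/3. Vectorized over rows when matrices are
#' supplied.
#'
#' @param donor,acceptor Dipole unit vectors (length-3 vectors or n x 3
#'   matrices).
#' @param separation Interdye vector(s), non-zero.
#' @return kappa^2 value(s).
#' @examples
#' kappa_squared(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)) # 1
#' kappa_squared(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)) # 4
#' @export
kappa_squared <- function(donor, acceptor, separation) {
  if (is.null(dim(donor))) donor <- matrix(donor, ncol = 3)
  if (is.null(dim(acceptor))) acceptor <- matrix(acceptor, ncol = 3)
  if (is.null(dim(separation))) separation <- matrix(separation, ncol = 3)
  rn <- sqrt(rowSums(separation^2))
  stop_if(any(rn == 0), "separation vector must be non-zero")
  rhat <- separation / rn
  dd <- rowSums(donor * acceptor)
  dr <- rowSums(donor * rhat)
  ar <- rowSums(acceptor * rhat)
  (dd - 3 * dr * ar)^2
}

#' Instantaneous energy-transfer rate
#'
#' k_F = kD (kappa^2 / (2/3)) (R0 / r)^6: at r = R0 and isotropic kappa^2
#' the transfer rate equals the donor decay rate.
#'
#' @param r Interdye distance(s) (nm), positive.
#' @param kappa2 Orientational factor(s).
#' @param cfg A [fret_config()].
#' @return Transfer rate(s) (1/ns).
#' @export
transfer_rate <- function(r, kappa2, cfg = fret_config()) {
  stop_if(any(r <= 0), "r must be positive")
  cfg$kD * (kappa2 / (2 / 3)) * (cfg$R0 / r)^6
}

#' Donor excited-state survival probability
#'
#' Averages exp(-integral of \[kD + kF(t')\]) over all excitation origins t0
#' that have a full `t_max` window of trajectory ahead, with the integral
#' discretized by the trapezoidal rule on the frame grid. Frames whose
#' minimum donor-acceptor heavy-atom distance is below the quench cutoff are
#' treated as nonemissive: in mode `"absorb"` the survival drops to zero at
#' the first quenched frame after the origin (the origin counts as a
#' transfer event); in mode `"exclude"` such origins are dropped from the
#' average.
#'
#' @param traj A [dye_trajectory()] longer than `t_max`.
#' @param cfg A [fret_config()].
#' @param quench `"absorb"` (default) or `"exclude"`.
#' @return An object of class `"donor_decay"`: `time` (ns), `p` (survival,
#'   p(0) = 1, non-increasing), `n_origins`, `kD`.
#' @export
donor_survival <- function(traj, cfg = fret_config(),
                           quench = c("absorb", "exclude")) {
  stopifnot(inherits(traj, "dye_trajectory"))
  quench <- match.arg(quench)
  dt <- traj$dt_out
  n <- length(traj$r)
  m <- floor(cfg$t_max / dt) # offsets per window
  stop_if(n <= m, "trajectory shorter than t_max")
  k2 <- kappa_squared(traj$donor, traj$acceptor, traj$separation)
  ktot <- cfg$kD + transfer_rate(traj$r, k2, cfg)
  quenched <- traj$min_DA < cfg$quench_cutoff
  n0 <- n - m # usable origins
  if (quench == "absorb") {
    # a quenched frame absorbs the excitation: make the local rate huge so
    # every window passing through it has zero survival beyond that frame
    ktot[quenched] <- 1e6
    Icum <- cumtrapz(seq_len(n) * dt, ktot)
    p <- vapply(0:m, function(j) {
      mean(exp(-(Icum[(1 + j):(n0 + j)] - Icum[1:n0])))
    }, numeric(1))
    origins <- n0
  } else {
    Icum <- cumtrapz(seq_len(n) * dt, ktot)
    qc <- cumsum(quenched)
    keep <- (qc[(1 + m):n] - c(0, qc)[1:n0]) == 0 # no quench inside window
    stop_if(!any(keep), "all origins quenched; nothing to average")
    idx <- which(keep)
    p <- vapply(0:m, function(j) {
      mean(exp(-(Icum[idx + j] - Icum[idx])))
    }, numeric(1))
    origins <- length(idx)
  }
  structure(list(time = (0:m) * dt, p = p, n_origins = origins, kD = cfg$kD),
            class = "donor_decay")
}

#' Mean transfer efficiency from a donor decay
#'
#' <E> = 1 - kD * integral of the survival probability over \[0, t_max\]
#' (trapezoidal rule). Warns when the survival has not decayed below 1e-3 at
#' the horizon.
#'
#' @param decay A [donor_decay()] as returned by [donor_survival()].
#' @param cfg A [fret_config()] (supplies kD when the decay lacks it).
#' @return An object of class `"fret_result"`: `mean_E` plus bookkeeping.
#' @export
mean_efficiency <- function(decay, cfg = fret_config()) {
  stop_if(length(decay$p) == 0, "empty decay")
  kD <- if (!is.null(decay$kD)) decay$kD else cfg$kD
  if (tail(decay$p, 1) > 1e-3) {
    warning("survival probability > 1e-3 at t_max; integration horizon may be too short")
  }
  E <- 1 - kD * trapz(decay$time, decay$p)
  structure(list(mean_E = E, n_origins = decay$n_origins,
                 t_max = tail(decay$time, 1)), class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf("<fret_result> <E> = %.4f (%d origins, t_max = %g ns)\n",
              x$mean_E, x$n_origins, x$t_max))
  invisible(x)
}

#' Map a backbone distance to an effective interdye distance
#'
#' r = d ((N + 9) / N)^nu: accounts for dye and linker lengths by adding
#' nine effective residues to the sequence separation N, with polymer
#' scaling exponent nu.
#'
#' @param d C-alpha--C-alpha distance between the labeled residues (nm).
#' @param N Sequence separation of the labeling sites (residues).
#' @param nu Scaling exponent (default 0.6).
#' @return Effective interdye distance (nm).
#' @examples
#' dyeless_distance(2, 56) # ~2.187
#' @export
dyeless_distance <- function(d, N, nu = 0.6) {
  stop_if(any(d <= 0), "d must be positive")
  stop_if(any(N <= 0), "N must be positive")
  d * ((N + 9) / N)^nu
}

#' Static transfer efficiency of a distance
#'
#' E = 1 / (1 + (r/R0)^6), the isotropically averaged (kappa^2 = 2/3)
#' transfer efficiency of a fixed distance.
#'
#' @param r Distance(s) (nm), positive.
#' @param R0 Foerster radius (nm).
#' @return Efficiency value(s) in (0, 1).
#' @export
efficiency_of_distance <- function(r, R0 = 6.0) {
  stop_if(any(r <= 0), "r must be positive")
  1 / (1 + (r / R0)^6)
}

#' Weighted variance of per-frame transfer efficiencies
#'
#' Var\[E\] = <E^2>_w - <E>_w^2 under normalized frame weights: the variance
#' of the transfer-efficiency distribution corresponding to the underlying
#' distance distribution.
#'
#' @param per_frame_E Per-frame efficiencies (>= 2 frames).
#' @param weights Optional normalized weights (sum 1 within 1e-8); default
#'   uniform.
#' @return Variance (dimensionless).
#' @export
efficiency_variance <- function(per_frame_E, weights = NULL) {
  n <- length(per_frame_E)
  stop_if(n < 2, "need at least 2 frames")
  if (is.null(weights)) weights <- rep(1 / n, n)
  stop_if(abs(sum(weights) - 1) > 1e-8, "weights must be normalized to 1")
  m1 <- sum(weights * per_frame_E)
  sum(weights * per_frame_E^2) - m1^2
}
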