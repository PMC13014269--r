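#' Read and write pipeline objects as tab-separated text
#'
#' Plain-text interchange formats: distance trajectories as
#' `time_ns<TAB>r_nm`, photon streams as `t_ns<TAB>channel` (channel D or
#' A), correlation curves as `lag_ns<TAB>G<TAB>err`, weighted ensembles as
#' `frame E N_EK N_ER N_DK N_DR weight` and diffusion landscapes as
#' `bin_center_nm F_kT D_nm2_per_ns` (per-interface diffusivities are
#' written at the left interface of each bin, the first bin repeating the
#' first interface value).
#'
#' @param x Object to write.
#' @param path File path.
#' @return The read object, or (for writers) `path` invisibly.
#' @name dynabuffer-io
NULL

#' @rdname dynabuffer-io
#' @export
write_distance_trajectory <- function(x, path) {
  stopifnot(inherits(x, "distance_trajectory"))
  df <- data.frame(time_ns = seq_along(x$values) * x$dt_out, r_nm = x$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dynabuffer-io
#' @export
read_distance_trajectory <- function(path) {
  df <- read.delim(path)
  stop_if(!all(c("time_ns", "r_nm") %in% names(df)),
          "expected columns time_ns and r_nm")
  dts <- diff(df$time_ns)
  stop_if(max(abs(dts - dts[1])) > 1e-6 * dts[1], "non-uniform sampling")
  distance_trajectory(df$r_nm, dts[1], label = basename(path))
}

#' @rdname dynabuffer-io
#' @export
write_photon_stream <- function(x, path) {
  stopifnot(inherits(x, "photon_stream"))
  write.table(data.frame(t_ns = x$times, channel = x$channel), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dynabuffer-io
#' @export
read_photon_stream <- function(path) {
  df <- read.delim(path)
  stop_if(!all(c("t_ns", "channel") %in% names(df)),
          "expected columns t_ns and channel")
  stop_if(!all(df$channel %in% c("D", "A")), "channel must be D or A")
  structure(list(times = df$t_ns, channel = as.character(df$channel),
                 duration = max(df$t_ns)), class = "photon_stream")
}

#' @rdname dynabuffer-io
#' @export
write_correlation_curve <- function(x, path) {
  stopifnot(inherits(x, "correlation_curve"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname dynabuffer-io
#' @export
read_correlation_curve <- function(path) {
  df <- read.delim(path)
  stop_if(!all(c("lag_ns", "G") %in% names(df)),
          "expected columns lag_ns and G")
  correlation_curve(df$lag_ns, df$G,
                    err = if ("err" %in% names(df)) df$err else NA_real_)
}

#' @rdname dynabuffer-io
#' @export
write_weighted_ensemble <- function(x, path) {
  stopifnot(inherits(x, "weighted_ensemble"))
  df <- data.frame(frame = seq_along(x$E), E = x$E,
                   N_EK = x$counts[, "EK"], N_ER = x$counts[, "ER"],
                   N_DK = x$counts[, "DK"], N_DR = x$counts[, "DR"],
                   weight = x$weights)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dynabuffer-io
#' @export
read_weighted_ensemble <- function(path) {
  df <- read.delim(path)
  need <- c("E", "N_EK", "N_ER", "N_DK", "N_DR", "weight")
  stop_if(!all(need %in% names(df)), "missing ensemble columns")
  weighted_ensemble(df$E, as.matrix(df[, c("N_EK", "N_ER", "N_DK", "N_DR")]),
                    weights = df$weight, label = basename(path))
}

#' @rdname dynabuffer-io
#' @export
write_diffusion_landscape <- function(x, path) {
  stopifnot(inherits(x, "diffusion_landscape"))
  nb <- x$grid$n_bins
  Dv <- if (length(x$D) == 1) rep(x$D, nb) else c(x$D[1], x$D)
  df <- data.frame(bin_center_nm = x$grid$centers, F_kT = x$F,
                   D_nm2_per_ns = Dv)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dynabuffer-io
#' @export
read_diffusion_landscape <- function(path) {
  df <- read.delim(path)
  need <- c("bin_center_nm", "F_kT", "D_nm2_per_ns")
  stop_if(!all(need %in% names(df)), "missing landscape columns")
  nb <- nrow(df)
  ctr <- df$bin_center_nm
  h <- ctr[2] - ctr[1]
  edges <- c(ctr - h / 2, ctr[nb] + h / 2)
  grid <- structure(list(edges = edges, centers = ctr, h = h,
                         n_bins = nb), class = "bin_grid")
  D <- df$D_nm2_per_ns
  Dif <- if (max(D) - min(D) < 1e-12) D[1] else D[-1]
  diffusion_landscape(df$F_kT, Dif, grid)
}

#' @rdname dynabuffer-io
#' @param traj A [dye_trajectory()].
#' @export
write_dye_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "dye_trajectory"))
  df <- data.frame(time_ns = seq_len(nrow(traj$donor)) * traj$dt_out,
                   dDx = traj$donor[, 1], dDy = traj$donor[, 2],
                   dDz = traj$donor[, 3], dAx = traj$acceptor[, 1],
                   dAy = traj$acceptor[, 2], dAz = traj$acceptor[, 3],
                   rx = traj$separation[, 1], ry = traj$separation[, 2],
                   rz = traj$separation[, 3], dmin_nm = traj$min_DA)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dynabuffer-io
#' @export
read_dye_trajectory <- function(path) {
  df <- read.delim(path)
  dts <- diff(df$time_ns)
  dye_trajectory(dts[1], unname(as.matrix(df[, c("dDx", "dDy", "dDz")])),
                 unname(as.matrix(df[, c("dAx", "dAy", "dAz")])),
                 unname(as.matrix(df[, c("rx", "ry", "rz")])), df$dmin_nm)
}
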