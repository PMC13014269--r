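#' Synthesize a two-channel photon stream
#'
#' Generates donor/acceptor photon arrival times from a transfer-efficiency
#' time series: photons arrive as a Poisson process at `mean_rate`
#' (optionally modulated by triplet blinking of the emitter), and each photon
#' is routed to the acceptor channel with probability E(t) at its arrival
#' time. Antibunching (suppression of closely spaced photon pairs) is off by
#' default and can be enabled with `antibunch_tau`.
#'
#' @param E Transfer-efficiency series in \[0, 1\], uniformly sampled.
#' @param dt Sampling interval of `E` (ns); total duration is `length(E)*dt`.
#' @param mean_rate Mean photon detection rate (photons/ns).
#' @param triplet Optional `list(amplitude =, lifetime =)`: fraction of time
#'   spent in the dark (triplet) state and the blinking correlation time (ns).
#' @param antibunch_tau If > 0, each photon suppresses the next with
#'   probability exp(-gap/antibunch_tau), mimicking antibunching.
#' @param seed Integer seed.
#' @return An object of class `"photon_stream"`: list with sorted `times`
#'   (ns), `channel` (character, "D"/"A") and `duration` (ns).
#' @export
synthesize_photon_stream <- function(E, dt, mean_rate, triplet = NULL,
                                     antibunch_tau = 0, seed = NULL) {
  if (inherits(E, "distance_trajectory")) {
    stop("pass an efficiency series; convert distances with efficiency_of_distance()")
  }
  stop_if(length(E) == 0, "efficiency series is empty")
  stop_if(mean_rate <= 0, "mean_rate must be positive")
  duration <- length(E) * dt
  with_seed(seed, {
    n <- rpois(1, mean_rate * duration)
    times <- sort(runif(n, 0, duration))
    if (!is.null(triplet) && triplet$amplitude > 0) {
      # two-state blinking: dark fraction a, correlation time tau_t
      a <- triplet$amplitude; tau_t <- triplet$lifetime
      k_off <- a / tau_t; k_on <- (1 - a) / tau_t
      t_edge <- 0; state <- runif(1) > a # TRUE = bright
      keep <- logical(length(times)); i <- 1
      while (t_edge < duration && i <= length(times)) {
        dwell <- rexp(1, if (state) k_off else k_on)
        t_next <- t_edge + dwell
        while (i <= length(times) && times[i] < t_next) {
          keep[i] <- state; i <- i + 1
        }
        state <- !state; t_edge <- t_next
      }
      times <- times[keep]
    }
    if (antibunch_tau > 0 && length(times) > 1) {
      keep <- logical(length(times)); keep[1] <- TRUE; last <- times[1]
      for (i in 2:length(times)) {
        gap <- times[i] - last
        if (runif(1) > exp(-gap / antibunch_tau)) {
          keep[i] <- TRUE; last <- times[i]
        }
      }
      times <- times[keep]
    }
    idx <- pmin(floor(times / dt) + 1, length(E))
    channel <- ifelse(runif(length(times)) < E[idx], "A", "D")
    structure(list(times = times, channel = channel, duration = duration),
              class = "photon_stream")
  })
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("<photon_stream> %d photons over %.1f ns (D: %d, A: %d)\n",
              length(x$times), x$duration, sum(x$channel == "D"),
              sum(x$channel == "A")))
  invisible(x)
}
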