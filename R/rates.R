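# Spike times -> smoothed, normalized 60-Hz firing-rate traces.

#' Bin spike times into a 60-Hz rate vector
#'
#' Bin b (0-based) covers [start + b/fs, start + (b+1)/fs); the value is
#' the spike count in the bin times `fs`, i.e. a rate in spikes/s. Spikes
#' outside the window are ignored; unsorted input is handled.
#'
#' @param spike_times Spike times, seconds.
#' @param window Numeric `c(start, end)`, half-open, seconds.
#' @param fs Bin rate, bins/s (default 60).
#' @return Numeric rate vector of length `round((end - start) * fs)`.
#' @export
bin_spikes <- function(spike_times, window, fs = FRAME_RATE) {
  n_bins <- as.integer(round((window[2] - window[1]) * fs))
  if (n_bins <= 0) stop("empty binning window")
  counts <- integer(n_bins)
  b <- floor((spike_times - window[1]) * fs)
  b <- b[b >= 0 & b < n_bins]
  if (length(b)) {
    tb <- tabulate(b + 1L, nbins = n_bins)
    counts <- tb
  }
  counts * fs
}

#' Gaussian-smooth a rate trace
#'
#' Convolves with a unit-area Gaussian kernel of full width at half
#' maximum `width_ms` (sigma = width / (2 sqrt(2 ln 2))), truncated at
#' +/- 4 sigma. Edges are handled by renormalizing the kernel over its
#' valid support, so a constant trace stays exactly constant.
#'
#' @param rate Rate vector at `fs` bins/s.
#' @param width_ms Kernel FWHM in milliseconds (default 300).
#' @param fs Bin rate, bins/s.
#' @return Smoothed vector, same length as the input.
#' @export
smooth_rate <- function(rate, width_ms = 300, fs = FRAME_RATE) {
  if (width_ms <= 0) stop("width_ms must be > 0")
  sigma_bins <- width_ms / 1000 / (2 * sqrt(2 * log(2))) * fs
  half <- max(1L, as.integer(ceiling(4 * sigma_bins)))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(rate)
  if (n == 0) return(rate)
  # direct convolution with zero padding; renormalize by the convolved
  # kernel mass so edges keep unit effective kernel area
  pad <- rep(0, half)
  num <- stats::filter(c(pad, rate, pad), k, sides = 2)[half + seq_len(n)]
  den <- stats::filter(c(pad, rep(1, n), pad), k, sides = 2)[half + seq_len(n)]
  as.numeric(num / den)
}

#' Per-unit session rate traces
#'
#' Bins every unit's spikes over the whole session at 60 Hz and smooths
#' them; the result is the common input of the classifier, running and
#' tuning analyses.
#'
#' @param session A `pertflow_session`.
#' @param smooth_width_ms Gaussian FWHM for the smoothed traces, ms.
#' @return List of class `rate_matrix`: `raw` and `smoothed` matrices
#'   (units x bins), `fs`, `t0 = 0`, and `normalization_state = "raw"`.
#' @export
session_rates <- function(session, smooth_width_ms = 300) {
  window <- c(0, session$duration)
  raw <- t(vapply(session$units, function(u)
    bin_spikes(u$spike_times, window), numeric(round(session$duration * FRAME_RATE))))
  smoothed <- t(apply(raw, 1, smooth_rate, width_ms = smooth_width_ms))
  structure(list(raw = raw, smoothed = smoothed, fs = FRAME_RATE, t0 = 0,
                 normalization_state = "raw",
                 session_max = apply(smoothed, 1, max)),
            class = "rate_matrix")
}

#' Normalize each unit by its session-wide maximum smoothed rate
#'
#' Units with zero maximum (silent units) are left at zero and flagged.
#' Idempotent: normalizing an already-normalized matrix is a no-op.
#'
#' @param rates A `rate_matrix` from [session_rates()].
#' @return The `rate_matrix` with `smoothed` scaled per unit into [0, 1],
#'   `normalization_state = "session_max_normalized"`, the scale kept in
#'   `session_max`, and a logical `silent` flag per unit.
#' @export
normalize_by_session_max <- function(rates) {
  if (identical(rates$normalization_state, "session_max_normalized"))
    return(rates)
  mx <- apply(rates$smoothed, 1, max)
  silent <- mx <= 0
  scale <- ifelse(silent, 1, mx)
  rates$smoothed <- rates$smoothed / scale
  rates$session_max <- mx
  rates$silent <- silent
  rates$normalization_state <- "session_max_normalized"
  rates
}

window_bins <- function(window, fs = FRAME_RATE, t0 = 0, n = NULL) {
  # bins whose left edge lies in [start, end); edges are frame-aligned so
  # round() removes floating-point jitter
  b0 <- as.integer(round((window[1] - t0) * fs))
  b1 <- as.integer(round((window[2] - t0) * fs)) - 1L
  if (b1 < b0) stop("empty window")
  idx <- (b0:b1) + 1L
  if (!is.null(n)) idx <- idx[idx >= 1 & idx <= n]
  idx
}

#' Mean rate over a time window
#'
#' Arithmetic mean of the bins whose left edge lies in the half-open
#' window.
#'
#' @param trace Rate vector at `fs` bins/s starting at `t0`.
#' @param window Numeric `c(start, end)`, seconds.
#' @param fs Bin rate; `t0` trace start time.
#' @return Mean rate (same units as the trace).
#' @export
window_mean <- function(trace, window, fs = FRAME_RATE, t0 = 0) {
  mean(trace[window_bins(window, fs, t0, length(trace))])
}

#' @rdname window_mean
#' @export
window_sum <- function(trace, window, fs = FRAME_RATE, t0 = 0) {
  sum(trace[window_bins(window, fs, t0, length(trace))])
}

#' Export a rate matrix as long-format CSV
#'
#' @param rates A `rate_matrix`.
#' @param path Output CSV path (columns unit, bin, rate; smoothed trace).
#' @return Invisibly, `path`.
#' @export
write_rates_csv <- function(rates, path) {
  m <- rates$smoothed
  df <- data.frame(unit = rep(seq_len(nrow(m)), each = ncol(m)),
                   bin = rep(seq_len(ncol(m)) - 1L, nrow(m)),
                   rate = as.vector(t(m)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
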