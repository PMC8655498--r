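# Spike-waveform typing: trough-to-peak duration and PCA + 2-means
# clustering into putative regular- and fast-spiking units.

#' Trough-to-peak duration of a mean spike waveform
#'
#' Time from the global minimum (trough) to the successive maximum. The
#' trough must be the dominant deflection (strictly negative and at least
#' as large in magnitude as the largest positive deflection) and must not
#' sit on the first or last sample; otherwise the waveform is rejected.
#' If no turning point follows the trough (the post-trough segment is
#' monotonically rising to the end), the trough-to-end duration is
#' returned with `flagged = TRUE`.
#'
#' @param waveform Numeric mean waveform.
#' @param fs Sampling rate, Hz.
#' @return List: `ttp_ms`, `trough_index`, `peak_index`, `flagged`.
#' @export
trough_to_peak <- function(waveform, fs) {
  n <- length(waveform)
  i0 <- which.min(waveform)
  if (i0 == 1L || i0 == n || waveform[i0] >= 0 ||
      abs(waveform[i0]) < max(waveform))
    stop("waveform has no dominant trough")
  after <- waveform[(i0 + 1L):n]
  j <- i0 + which.max(after)
  flagged <- j == n  # rising to the end: no local maximum found
  list(ttp_ms = (j - i0) / fs * 1000, trough_index = i0, peak_index = j,
       flagged = flagged)
}

resample_waveform <- function(w, fs_in, fs_out, n_out) {
  t_in <- (seq_along(w) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, w, xout = pmin(t_out, max(t_in)), rule = 2)$y
}

#' Classify units as putative regular- or fast-spiking
#'
#' Mean waveforms are resampled to a common 30-kHz grid, aligned at the
#' trough, amplitude-normalized (trough depth 1), and projected onto
#' their first three principal components; a 2-means partition (with a
#' deterministic farthest-point initialization) splits the cohort, and
#' the cluster with the smaller mean trough-to-peak duration is labeled
#' fast-spiking.
#'
#' @param waveforms List of numeric waveforms, or a units x samples
#'   matrix.
#' @param fs Sampling rate(s), Hz (scalar or per unit).
#' @return data.frame per unit: `trough_to_peak_ms`, `cluster`
#'   (`"regular"`/`"fast"`), `pc1`..`pc3`, plus attributes
#'   `variance_explained` (fraction by 3 PCs) and `degenerate`.
#' @export
classify_spiking_type <- function(waveforms, fs = 30000) {
  if (is.matrix(waveforms)) waveforms <- asplit(waveforms, 1)
  n <- length(waveforms)
  if (n < 2) stop("need at least 2 units to cluster")
  fs <- rep_len(fs, n)
  fs_out <- 30000
  n_out <- max(vapply(seq_len(n), function(i)
    as.integer(round(length(waveforms[[i]]) * fs_out / fs[i])), integer(1)))
  W <- t(vapply(seq_len(n), function(i)
    resample_waveform(as.numeric(waveforms[[i]]), fs[i], fs_out, n_out),
    numeric(n_out)))
  ttp <- vapply(seq_len(n), function(i) trough_to_peak(W[i, ], fs_out)$ttp_ms,
                numeric(1))
  # align troughs to the median trough index and normalize trough depth
  ti <- apply(W, 1, which.min)
  target <- as.integer(round(stats::median(ti)))
  Wa <- t(vapply(seq_len(n), function(i) {
    s <- ti[i] - target
    w <- if (s > 0) c(W[i, -(seq_len(s))], rep(W[i, n_out], s))
         else if (s < 0) c(rep(W[i, 1], -s), W[i, seq_len(n_out + s)])
         else W[i, ]
    w / abs(min(w))
  }, numeric(n_out)))
  total_var <- sum(apply(Wa, 2, stats::var))
  if (!is.finite(total_var) || total_var < 1e-12) {
    out <- data.frame(trough_to_peak_ms = ttp, cluster = "regular",
                      pc1 = 0, pc2 = 0, pc3 = 0)
    attr(out, "degenerate") <- TRUE
    attr(out, "variance_explained") <- NA_real_
    return(out)
  }
  pc <- stats::prcomp(Wa, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  varexp <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  # deterministic farthest-point initialization
  d0 <- rowSums(scale(scores, scale = FALSE)^2)
  c1 <- scores[which.max(d0), ]
  d1 <- rowSums(sweep(scores, 2, c1)^2)
  c2 <- scores[which.max(d1), ]
  km <- stats::kmeans(scores, centers = rbind(c1, c2), iter.max = 100)
  mean_ttp <- tapply(ttp, km$cluster, mean)
  fast_cluster <- as.integer(names(mean_ttp)[which.min(mean_ttp)])
  out <- data.frame(
    trough_to_peak_ms = ttp,
    cluster = ifelse(km$cluster == fast_cluster, "fast", "regular"),
    pc1 = scores[, 1], pc2 = if (k >= 2) scores[, 2] else 0,
    pc3 = if (k >= 3) scores[, 3] else 0)
  attr(out, "variance_explained") <- varexp
  attr(out, "degenerate") <- FALSE
  out
}

#' Waveform classification of a session's units
#'
#' @param session A `pertflow_session`.
#' @return The [classify_spiking_type()] table with `unit_id` prepended.
#' @export
analyze_waveforms <- function(session) {
  out <- classify_spiking_type(lapply(session$units, `[[`, "waveform"),
                               fs = vapply(session$units, `[[`, numeric(1),
                                           "waveform_fs"))
  res <- cbind(unit_id = vapply(session$units, `[[`, numeric(1), "unit_id"), out)
  attr(res, "variance_explained") <- attr(out, "variance_explained")
  attr(res, "degenerate") <- attr(out, "degenerate")
  res
}
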