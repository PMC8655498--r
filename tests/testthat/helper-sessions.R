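# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small mixed cohort on the standard 160-trial protocol
small_session <- function() {
  fixture("small", function() generate_session(cohort_config(n_units = 6), seed = 101))
}

small_rates <- function() {
  fixture("small_rates", function() session_rates(small_session()$session))
}

# untuned, locomotion-free cohort where the target MI is realized on every
# trial (the clean parameter-recovery condition)
recovery_config <- function(mi, n_units = 1, baseline = 10) {
  cohort_config(n_units = n_units, baseline_rate = baseline, evoked_rate = 8,
                orientation_kappa = 0, direction_ratio = 1, pref_tf = 3,
                running_gain = 1, running_pert_gain = 1,
                perturbation_mi = mi, couple_tf_mi = FALSE)
}

# brute-force windowed statistics used as independent oracles
oracle_window_mean <- function(trace, window, fs = 60, t0 = 0) {
  edges <- (seq_along(trace) - 1) / fs + t0
  mean(trace[edges >= window[1] & edges < window[2] - 1e-12])
}

oracle_window_sum <- function(trace, window, fs = 60, t0 = 0) {
  edges <- (seq_along(trace) - 1) / fs + t0
  sum(trace[edges >= window[1] & edges < window[2] - 1e-12])
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

oracle_gauss_smooth <- function(x, width_ms = 300, fs = 60) {
  sigma <- width_ms / 1000 / (2 * sqrt(2 * log(2))) * fs
  half <- max(1, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma); k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    out[i] <- sum(x[j[ok]] * k[ok]) / sum(k[ok])
  }
  out
}
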