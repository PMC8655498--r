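# Locomotor-state analysis: split perturbation trials by running speed,
# compute the summed-rate modulation per state, bootstrap its
# significance, and apply the mismatch-neuron criterion.

#' Split perturbation trials by locomotor state
#'
#' A perturbation trial is a running trial when the mean speed over the
#' pre-perturbation second plus the perturbation period is at least
#' 2 cm/s (the threshold value itself counts as running); otherwise it is
#' stationary. Trials with missing speed coverage are excluded.
#'
#' @param session A `pertflow_session`.
#' @param threshold Speed threshold, cm/s (default 2).
#' @param reducer Window reducer applied to the speed samples; default
#'   `mean` (alternatives: `min`, `max`).
#' @return List with integer trial-table row indices `running` and
#'   `stationary` (perturbation trials only), and `excluded`.
#' @export
split_trials_by_running <- function(session, threshold = 2, reducer = mean) {
  trials <- session$trials
  pert_rows <- which(trials$has_perturbation)
  speed <- session$running$speed
  fs <- session$running$fs
  run <- still <- excl <- integer(0)
  for (i in pert_rows) {
    w <- epoch_windows(as.list(trials[i, ]))
    idx <- window_bins(c(w$pre_perturbation[1], w$perturbation[2]), fs)
    if (any(idx > length(speed))) { excl <- c(excl, i); next }
    if (reducer(speed[idx]) >= threshold) run <- c(run, i) else still <- c(still, i)
  }
  list(running = run, stationary = still, excluded = excl)
}

#' Aligned perturbation-trial traces
#'
#' Extracts, for the given trials, the unit's trace aligned at
#' perturbation onset: `n_pre` pre-perturbation bins and `n_pert`
#' perturbation bins. Because perturbation durations vary from trial to
#' trial, `n_pert` defaults to the minimum duration across the trials.
#'
#' @param trace Session-long rate trace at 60 bins/s.
#' @param trials Trial-table rows (perturbation trials).
#' @param n_pre Pre-perturbation bins (default 60 = 1 s).
#' @param n_pert Perturbation bins; default min duration across trials.
#' @return List with matrices `pre` (trials x n_pre) and `pert`
#'   (trials x n_pert).
#' @export
aligned_pert_traces <- function(trace, trials, n_pre = 60L, n_pert = NULL) {
  if (nrow(trials) == 0) stop("no trials to align")
  if (is.null(n_pert)) n_pert <- min(trials$pert_dur_frames)
  pre <- matrix(NA_real_, nrow(trials), n_pre)
  pert <- matrix(NA_real_, nrow(trials), n_pert)
  for (i in seq_len(nrow(trials))) {
    f_on <- as.integer(round(trials$onset_time[i] * FRAME_RATE)) +
      trials$pert_onset_frame[i]
    pre[i, ] <- trace[f_on - n_pre + seq_len(n_pre)]
    pert[i, ] <- trace[f_on + seq_len(n_pert)]
  }
  list(pre = pre, pert = pert)
}

#' Summed-rate modulation of a condition-averaged trace
#'
#' Sum of the condition-averaged rate over the perturbation window minus
#' the sum over the preceding 1-s window (the area between the response
#' curve and its pre-perturbation level, in summed-rate units).
#'
#' @param avg_pre Condition-averaged pre-perturbation trace (>= 60 bins).
#' @param avg_pert Condition-averaged perturbation-window trace.
#' @return Scalar modulation (summed-rate units).
#' @export
condition_modulation <- function(avg_pre, avg_pert) {
  if (length(avg_pre) < 60) stop("need at least 1 s (60 bins) of pre-perturbation data")
  sum(avg_pert) - sum(avg_pre[length(avg_pre) - 60 + seq_len(60)])
}

#' Bootstrap test of running enhancement
#'
#' Per bootstrap draw, 20 trials are resampled with replacement from each
#' condition, averaged, and the peak and the mean of the averaged trace
#' over the perturbation window are computed per condition. The unit is
#' significantly running-modulated when the running condition exceeds the
#' stationary one on BOTH statistics in at least 95% of draws
#' (950/1000 at the default resolution).
#'
#' @param run_pert,still_pert Trial x bin matrices of perturbation-window
#'   traces for running and stationary trials.
#' @param n_resample Trials drawn per condition per bootstrap (default 20).
#' @param n_boot Bootstrap draws (default 1000).
#' @return List: `significant`, `n_win` (draws where running won on both
#'   statistics), `n_boot`, `criterion` (the >= 0.95 count threshold).
#' @export
bootstrap_running_significance <- function(run_pert, still_pert,
                                           n_resample = 20L, n_boot = 1000L) {
  if (nrow(run_pert) == 0 || nrow(still_pert) == 0) stop("empty condition")
  crit <- as.integer(ceiling(0.95 * n_boot))
  n_win <- 0L
  for (b in seq_len(n_boot)) {
    r <- colMeans(run_pert[sample.int(nrow(run_pert), n_resample, replace = TRUE), ,
                           drop = FALSE])
    s <- colMeans(still_pert[sample.int(nrow(still_pert), n_resample, replace = TRUE), ,
                             drop = FALSE])
    if (max(r) > max(s) && mean(r) > mean(s)) n_win <- n_win + 1L
  }
  list(significant = n_win >= crit, n_win = n_win, n_boot = n_boot,
       criterion = crit)
}

#' Mismatch-like classification of a unit
#'
#' A unit is mismatch-like when it is reliably positively modulated by
#' the perturbation and its running-state modulation is at least twice
#' the stationary one (stationary modulation clipped at 0 to avoid sign
#' pathologies).
#'
#' @param sign Unit's perturbation sign (`"positive"`/`"negative"`/`"none"`).
#' @param mi_run,mi_still Condition modulations ([condition_modulation()]).
#' @return Logical flag.
#' @export
classify_mismatch_like <- function(sign, mi_run, mi_still) {
  identical(sign, "positive") && !is.na(mi_run) && mi_run > 0 &&
    mi_run >= 2 * max(mi_still, 0, na.rm = TRUE)
}

#' Running-state analysis of every unit in a session
#'
#' Splits perturbation trials by locomotor state; sessions (unit sets)
#' with fewer than `min_trials` trials in either condition yield no
#' result (all fields NA). For eligible data, computes the per-condition
#' summed-rate modulation on normalized condition-averaged traces, the
#' bootstrap running-significance flag, and the mismatch-like flag
#' (using perturbation signs from `pert_table` when given).
#'
#' @param session A `pertflow_session`.
#' @param rates Optional precomputed [session_rates()].
#' @param pert_table Per-unit table from [analyze_perturbation()] (for
#'   the `sign` column); optional.
#' @param min_trials Minimum trials per condition (default 4).
#' @param n_resample,n_boot Bootstrap parameters.
#' @param seed Optional RNG seed.
#' @return data.frame per unit: mi_run, mi_still, n_run, n_still,
#'   significant_running, mismatch_like.
#' @export
analyze_running <- function(session, rates = NULL, pert_table = NULL,
                            min_trials = 4L, n_resample = 20L, n_boot = 1000L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rates)) rates <- session_rates(session)
  norm <- normalize_by_session_max(rates)
  split <- split_trials_by_running(session)
  n_run <- length(split$running); n_still <- length(split$stationary)
  n_units <- length(session$units)
  out <- data.frame(unit_id = vapply(session$units, `[[`, numeric(1), "unit_id"),
                    mi_run = NA_real_, mi_still = NA_real_,
                    n_run = n_run, n_still = n_still,
                    significant_running = NA, mismatch_like = NA)
  if (n_run < min_trials || n_still < min_trials) return(out)
  run_tr <- session$trials[split$running, ]
  still_tr <- session$trials[split$stationary, ]
  n_pert <- min(c(run_tr$pert_dur_frames, still_tr$pert_dur_frames))
  for (i in seq_len(n_units)) {
    tr <- norm$smoothed[i, ]
    ar <- aligned_pert_traces(tr, run_tr, n_pert = n_pert)
    as_ <- aligned_pert_traces(tr, still_tr, n_pert = n_pert)
    out$mi_run[i] <- condition_modulation(colMeans(ar$pre), colMeans(ar$pert))
    out$mi_still[i] <- condition_modulation(colMeans(as_$pre), colMeans(as_$pert))
    bt <- bootstrap_running_significance(ar$pert, as_$pert, n_resample, n_boot)
    out$significant_running[i] <- bt$significant
    sign_i <- if (is.null(pert_table)) "positive" else pert_table$sign[i]
    out$mismatch_like[i] <- classify_mismatch_like(sign_i, out$mi_run[i],
                                                   out$mi_still[i])
  }
  out
}
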