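# Behavioral analysis: the perturbation-reliability machinery applied to
# the running-speed trace, and the trial-by-trial correlation between
# neural and speed modulation.

#' Speed-change reliability of a session
#'
#' Treats the session's running-speed trace exactly like a neural rate
#' trace: normalizes by the session maximum, computes the six classifier
#' features per grating trial over the same epoch windows, fits the
#' logistic trial classifier, and compares its AUC against a
#' label-shuffle null (95th-percentile rule). Also returns the per-trial
#' speed modulation index of perturbation trials (raw speed, floor
#' `eps_speed`).
#'
#' @param session A `pertflow_session`.
#' @param n_shuffles Label shuffles for the null.
#' @param eps_speed Speed floor for the MI denominator, cm/s (default 0.5).
#' @param seed Optional RNG seed.
#' @return List (class `speed_change_result`): `auc`, `null_p95`,
#'   `reliable`, `per_trial` (trial_id, speed_mi), `evaluable`.
#' @export
speed_change_analysis <- function(session, n_shuffles = 1000, eps_speed = 0.5,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  speed <- session$running$speed
  mx <- max(speed)
  if (mx <= 0 || stats::sd(speed) == 0)  # flat trace carries no information
    return(structure(list(evaluable = FALSE), class = "speed_change_result"))
  sn <- speed / mx
  eps_norm <- eps_speed / mx
  tw <- session_trial_windows(session)
  trials <- tw$trials
  feats <- features_from_windows(sn, tw, eps_norm)
  y <- as.integer(trials$has_perturbation)
  if (sum(y == 1) < 2 || sum(y == 0) < 2 || all(apply(feats, 2, stats::sd) == 0))
    return(structure(list(evaluable = FALSE), class = "speed_change_result"))
  fit <- fit_trial_classifier(feats, y)
  auc <- roc_auc(fit$scores, y)
  null_auc <- shuffle_null(feats, y, n_shuffles)
  p95 <- stats::quantile(null_auc, 0.95, names = FALSE, type = 7)
  pt <- trials[trials$has_perturbation, ]
  mi <- vapply(seq_len(nrow(pt)), function(i) {
    w <- epoch_windows(as.list(pt[i, ]))
    modulation_index(window_mean(speed, w$perturbation),
                     window_mean(speed, w$pre_perturbation), eps = eps_speed)
  }, numeric(1))
  structure(list(evaluable = TRUE, auc = auc, null_p95 = p95,
                 reliable = auc > p95,
                 per_trial = data.frame(trial_id = pt$trial_id, speed_mi = mi)),
            class = "speed_change_result")
}

#' Correlation between neural and speed trial-by-trial modulation
#'
#' Pearson correlation, across perturbation trials, between a unit's
#' per-trial modulation indices and the per-trial speed modulation
#' indices; two-sided p-value, significance at `alpha`.
#'
#' @param neural_mi Per-trial neural MIs (perturbation trials).
#' @param speed_mi Per-trial speed MIs (same trials, same order).
#' @param alpha Significance level (default 0.05).
#' @return List: `r`, `p`, `significant`, `n`, `degenerate` (zero
#'   variance in either series).
#' @export
neural_speed_mi_correlation <- function(neural_mi, speed_mi, alpha = 0.05) {
  if (length(neural_mi) != length(speed_mi)) stop("length mismatch")
  ok <- is.finite(neural_mi) & is.finite(speed_mi)
  if (sum(ok) < 5) stop("need >= 5 perturbation trials with both MIs defined")
  x <- neural_mi[ok]; y <- speed_mi[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, significant = NA, n = sum(ok),
                degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < alpha, n = sum(ok), degenerate = FALSE)
}

#' Behavior analysis of a session: speed reliability + per-unit coupling
#'
#' @param session A `pertflow_session`.
#' @param pert_results Per-unit results from [analyze_perturbation()]
#'   (their `per_trial` MIs are correlated with the speed MIs).
#' @param n_shuffles Shuffles for the speed classifier null.
#' @param alpha Correlation significance level.
#' @param seed Optional RNG seed.
#' @return List with `speed` (the `speed_change_result`) and `table`
#'   (per unit: r, p, significant).
#' @export
analyze_behavior <- function(session, pert_results, n_shuffles = 1000,
                             alpha = 0.05, seed = NULL) {
  sp <- speed_change_analysis(session, n_shuffles = n_shuffles, seed = seed)
  tab <- NULL
  if (isTRUE(sp$evaluable)) {
    tab <- do.call(rbind, lapply(seq_along(pert_results$results), function(i) {
      r <- pert_results$results[[i]]
      if (!isTRUE(r$evaluable))
        return(data.frame(unit_id = i, r = NA_real_, p = NA_real_,
                          significant = NA))
      m <- merge(r$per_trial, sp$per_trial, by = "trial_id")
      cc <- neural_speed_mi_correlation(m$mi, m$speed_mi, alpha)
      data.frame(unit_id = i, r = cc$r, p = cc$p, significant = cc$significant)
    }))
  }
  list(speed = sp, table = tab)
}
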