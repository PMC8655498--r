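# Trial classification of perturbation responses: six windowed features
# per trial, in-sample logistic regression, ROC-AUC reliability against a
# label-shuffle null, and the modulation (MI) / depth-of-modulation (DM)
# indices.

#' Response modulation index
#'
#' MI = (Rpert - Rpre) / Rpre, the proportional rate change during the
#' perturbation relative to the preceding second. A rate floor `eps`
#' guards near-zero denominators; when both rates are 0 the index is 0.
#'
#' @param r_pert,r_pre Mean rates (>= 0), spikes/s (or any common scale).
#' @param eps Rate floor for the denominator, default 0.1 spikes/s.
#' @return MI, bounded below by -1 for nonnegative rates.
#' @export
modulation_index <- function(r_pert, r_pre, eps = 0.1) {
  if (any(r_pert < 0) || any(r_pre < 0)) stop("rates must be nonnegative")
  ifelse(r_pert == 0 & r_pre == 0, 0, (r_pert - r_pre) / pmax(r_pre, eps))
}

#' Depth of modulation
#'
#' DM = (Rpert - Rpre) / (Rpert + Rpre), bounded in [-1, 1]; 0 by
#' convention when both rates are 0.
#'
#' @inheritParams modulation_index
#' @return DM in [-1, 1].
#' @export
depth_of_modulation <- function(r_pert, r_pre) {
  if (any(r_pert < 0) || any(r_pre < 0)) stop("rates must be nonnegative")
  s <- r_pert + r_pre
  ifelse(s == 0, 0, (r_pert - r_pre) / s)
}

#' Six per-trial classifier features
#'
#' From a (session-max-normalized) rate trace and the trial's epoch
#' windows: the Rpert/Rpre ratio, their difference, the summed rates over
#' both windows, the summed perturbation-window rate, DM and MI. Rpert and
#' Rpre are window means; sums are over the per-bin values.
#'
#' @param trace Normalized rate trace (session-long), at `fs` bins/s.
#' @param windows Epoch windows from [epoch_windows()].
#' @param eps Rate floor (on the trace's scale) for ratio and MI.
#' @param fs,t0 Trace sampling rate and start time.
#' @return Named numeric vector of the six features.
#' @export
trial_features <- function(trace, windows, eps = 0.1, fs = FRAME_RATE, t0 = 0) {
  r_pre <- window_mean(trace, windows$pre_perturbation, fs, t0)
  r_pert <- window_mean(trace, windows$perturbation, fs, t0)
  s_pre <- window_sum(trace, windows$pre_perturbation, fs, t0)
  s_pert <- window_sum(trace, windows$perturbation, fs, t0)
  c(ratio = r_pert / max(r_pre, eps),
    difference = r_pert - r_pre,
    combined_sum = s_pre + s_pert,
    pert_sum = s_pert,
    dm = depth_of_modulation(r_pert, r_pre),
    mi = modulation_index(r_pert, r_pre, eps))
}

logistic_irls <- function(X, y, maxit = 25, tol = 1e-4) {
  # iteratively reweighted least squares for the binomial GLM; the
  # capped-iteration path keeps fitted probabilities well-defined under
  # complete separation
  beta <- numeric(ncol(X))
  eta <- drop(X %*% beta)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    beta <- .lm.fit(X * sw, z * sw)$coefficients
    eta <- drop(X %*% beta)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  list(fitted = 1 / (1 + exp(-eta)), converged = converged)
}

#' Fit the logistic trial classifier and score trials in-sample
#'
#' Features are z-scored (zero-variance columns dropped), a logistic
#' regression is fit by maximum likelihood (IRLS) on all trials, and the
#' fitted probabilities are returned as per-trial scores. Complete
#' separation is tolerated: the capped-iteration fit still yields
#' well-defined scores and is flagged.
#'
#' @param x Feature matrix (trials x features).
#' @param y Labels, 0/1 (1 = perturbation trial); >= 2 of each required.
#' @return List with `scores`, `converged`, `separation` flag.
#' @export
fit_trial_classifier <- function(x, y) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 trials of each label")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  keep <- is.finite(sd) & sd > 0
  xz <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  xd <- cbind(1, xz)
  fit <- logistic_irls(xd, y)
  sep <- all((fit$fitted > 0.5) == (y == 1))  # perfect in-sample separation
  list(scores = fit$fitted, converged = fit$converged, separation = sep)
}

#' ROC area under the curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random
#' positive-label score exceeds a random negative-label score, ties
#' counted half. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; at least one of each.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both labels to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Label-shuffle null distribution of the classifier AUC
#'
#' Permutes the trial labels, refits the classifier and records the
#' in-sample AUC, `n_shuffles` times. Because the null is built with the
#' same in-sample procedure as the real AUC, the optimism of in-sample
#' fitting cancels in the reliability comparison.
#'
#' @param x Feature matrix (trials x features).
#' @param y True labels (0/1).
#' @param n_shuffles Number of permutations (>= 1).
#' @return Numeric vector of null AUCs.
#' @export
shuffle_null <- function(x, y, n_shuffles = 1000) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  vapply(seq_len(n_shuffles), function(i) {
    ys <- sample(y)
    roc_auc(fit_trial_classifier(x, ys)$scores, ys)
  }, numeric(1))
}

# precomputed per-trial pre/perturbation bin indices for a session
# (grating trials only; virtual windows included), shared across units
session_trial_windows <- function(session) {
  trials <- session$trials[!session$trials$blank, ]
  f_on <- as.integer(round(trials$onset_time * FRAME_RATE)) + trials$pert_onset_frame
  list(trials = trials,
       pre_idx = lapply(f_on, function(f) f - 60L + seq_len(60L)),
       pert_idx = lapply(seq_len(nrow(trials)), function(i)
         f_on[i] + seq_len(trials$pert_dur_frames[i])))
}

features_from_windows <- function(trace, tw, eps) {
  n <- nrow(tw$trials)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("ratio", "difference", "combined_sum",
                                        "pert_sum", "dm", "mi")))
  for (i in seq_len(n)) {
    pre <- trace[tw$pre_idx[[i]]]; pert <- trace[tw$pert_idx[[i]]]
    r_pre <- mean(pre); r_pert <- mean(pert)
    s <- r_pert + r_pre
    out[i, ] <- c(r_pert / max(r_pre, eps), r_pert - r_pre,
                  sum(pre) + sum(pert), sum(pert),
                  if (s == 0) 0 else (r_pert - r_pre) / s,
                  if (r_pert == 0 && r_pre == 0) 0
                  else (r_pert - r_pre) / max(r_pre, eps))
  }
  out
}

unit_feature_matrix <- function(trace_norm, session, eps_norm, tw = NULL) {
  if (is.null(tw)) tw <- session_trial_windows(session)
  feats <- features_from_windows(trace_norm, tw, eps_norm)
  list(x = feats, y = as.integer(tw$trials$has_perturbation), trials = tw$trials)
}

#' Classify one unit as perturbation-responsive
#'
#' Computes the six features for every grating trial (virtual perturbation
#' windows on non-perturbation trials), fits the logistic classifier,
#' compares its in-sample AUC against a label-shuffle null, and summarizes
#' the unit's modulation. The unit is reliable when its AUC exceeds the
#' 95th percentile (linear-interpolation quantile) of the null. The
#' unit-level MI/DM are computed from across-trial mean raw rates of the
#' perturbation trials (perturbation window vs the preceding second, on
#' unsmoothed 60-Hz binned rates).
#'
#' @param trace_norm Session-long normalized smoothed trace of the unit.
#' @param trace_raw Session-long unsmoothed binned rate trace (spikes/s).
#' @param session The `pertflow_session`.
#' @param session_max The unit's session-max smoothed rate (normalization
#'   scale), used to put the rate floor on the normalized scale.
#' @param n_shuffles Number of label shuffles for the null (default 1000).
#' @param eps Rate floor in spikes/s (pre-normalization scale).
#' @param windows Optional precomputed per-trial window indices (internal;
#'   shared across units of a session).
#' @return List (class `perturbation_result`): `auc`, `null_auc`,
#'   `null_p95`, `reliable`, `mi_mean`, `dm_mean`, `sign`
#'   (positive/negative/none), `per_trial` data.frame with per-trial MI
#'   of perturbation trials (for the behavior correlation), and flags.
#' @export
classify_perturbation_unit <- function(trace_norm, trace_raw, session,
                                       session_max, n_shuffles = 1000,
                                       eps = 0.1, windows = NULL) {
  eps_norm <- if (session_max > 0) eps / session_max else eps
  if (is.null(windows)) windows <- session_trial_windows(session)
  fm <- unit_feature_matrix(trace_norm, session, eps_norm, tw = windows)
  if (sum(fm$y == 1) < 2 || sum(fm$y == 0) < 2)
    return(structure(list(evaluable = FALSE), class = "perturbation_result"))
  fit <- fit_trial_classifier(fm$x, fm$y)
  auc <- roc_auc(fit$scores, fm$y)
  null_auc <- shuffle_null(fm$x, fm$y, n_shuffles)
  p95 <- stats::quantile(null_auc, 0.95, names = FALSE, type = 7)
  reliable <- auc > p95
  # unit-level MI/DM from trial-averaged raw rates over perturbation trials
  is_pt <- fm$trials$has_perturbation
  pt <- fm$trials[is_pt, ]
  r_pre_t <- vapply(windows$pre_idx[is_pt], function(ix) mean(trace_raw[ix]),
                    numeric(1))
  r_pert_t <- vapply(windows$pert_idx[is_pt], function(ix) mean(trace_raw[ix]),
                     numeric(1))
  mi_mean <- modulation_index(mean(r_pert_t), mean(r_pre_t), eps)
  dm_mean <- depth_of_modulation(mean(r_pert_t), mean(r_pre_t))
  sign <- if (!reliable) "none" else if (mi_mean > 0) "positive" else "negative"
  structure(list(
    evaluable = TRUE, auc = auc, null_auc = null_auc, null_p95 = p95,
    reliable = reliable, mi_mean = mi_mean, dm_mean = dm_mean, sign = sign,
    separation = fit$separation,
    per_trial = data.frame(trial_id = pt$trial_id,
                           mi = modulation_index(r_pert_t, r_pre_t, eps),
                           r_pert = r_pert_t, r_pre = r_pre_t)
  ), class = "perturbation_result")
}

#' Perturbation-response analysis of every unit in a session
#'
#' @param session A `pertflow_session` (main protocol).
#' @param rates Optional precomputed [session_rates()] (raw state); built
#'   if missing.
#' @param n_shuffles Label shuffles per unit for the null (default 1000).
#' @param eps Rate floor, spikes/s.
#' @param seed Optional seed for the shuffle RNG.
#' @return List with `results` (per-unit `perturbation_result`s) and
#'   `table` (per-unit data.frame: unit_id, auc, null_p95, reliable,
#'   mi_mean, dm_mean, sign).
#' @export
analyze_perturbation <- function(session, rates = NULL, n_shuffles = 1000,
                                 eps = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rates)) rates <- session_rates(session)
  norm <- normalize_by_session_max(rates)
  tw <- session_trial_windows(session)
  results <- lapply(seq_along(session$units), function(i)
    classify_perturbation_unit(norm$smoothed[i, ], rates$raw[i, ], session,
                               norm$session_max[i], n_shuffles, eps,
                               windows = tw))
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (!isTRUE(r$evaluable))
      return(data.frame(unit_id = session$units[[i]]$unit_id, auc = NA_real_,
                        null_p95 = NA_real_, reliable = NA, mi_mean = NA_real_,
                        dm_mean = NA_real_, sign = NA_character_))
    data.frame(unit_id = session$units[[i]]$unit_id, auc = r$auc,
               null_p95 = r$null_p95, reliable = r$reliable,
               mi_mean = r$mi_mean, dm_mean = r$dm_mean, sign = r$sign)
  }))
  list(results = results, table = tab)
}
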