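# Orientation/direction tuning of grating and perturbation responses
# (vector-sum selectivity, Hotelling's T-squared, direction dot-product
# test) and temporal-frequency tuning from the accelerating-grating
# protocol.

DIRECTIONS_DEG <- seq(0, 315, by = 45)

#' Session baseline rate of a unit
#'
#' Mean rate over all time outside grating (non-blank) trials, i.e. the
#' inter-trial intervals and zero-contrast trials.
#'
#' @param trace Session-long raw rate trace at 60 bins/s.
#' @param session A `pertflow_session`.
#' @return Baseline rate, spikes/s.
#' @export
session_baseline_rate <- function(trace, session) {
  n <- length(trace)
  inside <- rep(FALSE, n)
  for (i in which(!session$trials$blank)) {
    tr <- session$trials[i, ]
    f0 <- as.integer(round(tr$onset_time * FRAME_RATE))
    idx <- f0 + seq_len(tr$n_frames)
    inside[idx[idx <= n]] <- TRUE
  }
  mean(trace[!inside])
}

#' Per-direction grating responses
#'
#' Mean rate in the first `response_window_s` seconds of each grating
#' trial, minus the session baseline; averaged per direction. Responses
#' may be negative.
#'
#' @param trace Session-long raw rate trace.
#' @param session A `pertflow_session` (main protocol).
#' @param response_window_s Response window, default 3.5 s.
#' @return List: `responses` named numeric (one per direction, deg),
#'   `per_trial` data.frame (trial_id, direction_deg, response),
#'   `baseline`.
#' @export
direction_responses <- function(trace, session, response_window_s = 3.5) {
  trials <- session$trials[!session$trials$blank, ]
  baseline <- session_baseline_rate(trace, session)
  resp <- vapply(seq_len(nrow(trials)), function(i) {
    w <- c(trials$onset_time[i], trials$onset_time[i] + response_window_s)
    window_mean(trace, w)
  }, numeric(1)) - baseline
  per_dir <- tapply(resp, factor(trials$direction_deg, levels = DIRECTIONS_DEG),
                    mean)
  list(responses = per_dir,
       per_trial = data.frame(trial_id = trials$trial_id,
                              direction_deg = trials$direction_deg,
                              response = resp),
       baseline = baseline)
}

vector_sum_selectivity <- function(R, period) {
  # period 2 for orientation (angles doubled), 1 for direction
  R <- pmax(R, 0)  # rectify so the normalized length stays in [0, 1]
  s <- sum(R)
  if (s <= 0) return(list(l = NA_real_, pref = NA_real_, untunable = TRUE))
  th <- DIRECTIONS_DEG * pi / 180
  z <- sum(R * exp(1i * period * th))
  ang <- (Arg(z) / period) * 180 / pi
  mod <- 360 / period
  list(l = Mod(z) / s, pref = ((ang %% mod) + mod) %% mod, untunable = FALSE)
}

#' Orientation selectivity (vector sum on doubled angles)
#'
#' L_ori = |sum_k R(theta_k) e^(2 i theta_k)| / sum_k R(theta_k), with
#' responses rectified at 0; the preferred orientation is half the
#' argument of the numerator, in [0, 180).
#'
#' @param R Named/plain numeric of length 8: responses at 0,45,...,315 deg.
#' @return List: `l_ori`, `pref_ori` (deg), `untunable` flag (all-zero
#'   rectified responses).
#' @export
orientation_selectivity <- function(R) {
  stopifnot(length(R) == 8)
  v <- vector_sum_selectivity(as.numeric(R), 2)
  list(l_ori = v$l, pref_ori = v$pref, untunable = v$untunable)
}

#' Direction selectivity (vector sum)
#'
#' L_dir = |sum_k R(theta_k) e^(i theta_k)| / sum_k R(theta_k), rectified;
#' preferred direction is the argument of the numerator, in [0, 360).
#'
#' @inheritParams orientation_selectivity
#' @return List: `l_dir`, `pref_dir` (deg), `untunable`.
#' @export
direction_selectivity <- function(R) {
  stopifnot(length(R) == 8)
  v <- vector_sum_selectivity(as.numeric(R), 1)
  list(l_dir = v$l, pref_dir = v$pref, untunable = v$untunable)
}

#' One-sample Hotelling's T-squared test of orientation tuning
#'
#' Each trial is mapped to the orientation-space vector
#' (r cos 2 theta, r sin 2 theta), r being the trial's baseline-
#' subtracted response; the test asks whether the population mean of
#' these 2-vectors differs from (0, 0), via the exact F transform of
#' T-squared. A singular covariance yields p = 1 with a degeneracy flag.
#'
#' @param response Per-trial responses (any real values).
#' @param direction_deg Per-trial stimulus directions, degrees.
#' @return List: `p`, `t2`, `degenerate`.
#' @export
hotelling_t2_orientation <- function(response, direction_deg) {
  n <- length(response)
  if (n < 3) stop("need at least 3 trials for Hotelling's T2")
  th <- direction_deg * pi / 180
  X <- cbind(response * cos(2 * th), response * sin(2 * th))
  m <- colMeans(X)
  S <- stats::cov(X)
  if (!all(is.finite(S)))
    return(list(p = 1, t2 = NA_real_, degenerate = TRUE))
  sv <- svd(S)
  tol <- max(sv$d) * 1e-12 + 1e-300
  if (any(sv$d <= tol)) {
    # singular covariance: zero variance along some axis. A nonzero mean
    # component in that axis is infinitely significant; otherwise p = 1.
    null_comp <- drop(t(sv$u[, sv$d <= tol, drop = FALSE]) %*% m)
    p_val <- if (sum(m^2) > 0 && any(abs(null_comp) > sqrt(sum(m^2)) * 1e-8)) 0 else 1
    return(list(p = p_val, t2 = NA_real_, degenerate = TRUE))
  }
  t2 <- n * drop(t(m) %*% solve(S, m))
  p_dim <- 2
  f <- (n - p_dim) / (p_dim * (n - 1)) * t2
  list(p = stats::pf(f, p_dim, n - p_dim, lower.tail = FALSE), t2 = t2,
       degenerate = FALSE)
}

#' Direction dot-product test
#'
#' Projects each trial's direction-space vector (r cos theta, r sin theta)
#' onto the unit vector at the preferred direction and one-sided t-tests
#' whether the projections exceed those onto the opposite direction
#' (equivalently, whether the projections onto the preferred direction
#' are positive on average).
#'
#' @param response Per-trial baseline-subtracted responses.
#' @param direction_deg Per-trial directions, degrees.
#' @param pref_dir Preferred direction estimate, degrees.
#' @return List: `p`, `t`, `degenerate` (zero-variance projections).
#' @export
direction_dot_product_test <- function(response, direction_deg, pref_dir) {
  if (length(response) < 3) stop("need at least 3 trials")
  th <- direction_deg * pi / 180
  u <- pref_dir * pi / 180
  proj <- response * cos(th) * cos(u) + response * sin(th) * sin(u)
  if (stats::sd(proj) == 0)
    return(list(p = if (mean(proj) > 0) 0 else 1, t = NA_real_, degenerate = TRUE))
  tt <- stats::t.test(proj, alternative = "greater", mu = 0)
  list(p = tt$p.value, t = unname(tt$statistic), degenerate = FALSE)
}

#' Full grating-tuning analysis of one unit
#'
#' @inheritParams direction_responses
#' @param alpha Significance level for the tuning tests (default 0.01).
#' @return List (class `tuning_result`): per-direction `responses`,
#'   `l_ori`, `l_dir`, `pref_ori`, `pref_dir`, `p_ori` (Hotelling),
#'   `p_dir` (dot product), significance flags, `untunable`.
#' @export
unit_tuning <- function(trace, session, response_window_s = 3.5, alpha = 0.01) {
  dr <- direction_responses(trace, session, response_window_s)
  osel <- orientation_selectivity(dr$responses)
  dsel <- direction_selectivity(dr$responses)
  ht <- hotelling_t2_orientation(dr$per_trial$response, dr$per_trial$direction_deg)
  dp <- if (dsel$untunable) list(p = NA_real_, degenerate = TRUE)
        else direction_dot_product_test(dr$per_trial$response,
                                        dr$per_trial$direction_deg, dsel$pref_dir)
  structure(list(
    responses = dr$responses, baseline = dr$baseline,
    l_ori = osel$l_ori, pref_ori = osel$pref_ori,
    l_dir = dsel$l_dir, pref_dir = dsel$pref_dir,
    p_ori = ht$p, p_dir = dp$p,
    ori_tuned = !is.na(ht$p) && ht$p < alpha,
    dir_tuned = !is.na(dp$p) && dp$p < alpha,
    untunable = osel$untunable
  ), class = "tuning_result")
}

fold_delta_ori <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Perturbation-response tuning of one unit
#'
#' Per-direction perturbation responses (perturbation-window mean rate
#' minus the session baseline, averaged over the perturbation trials of
#' each direction). Because perturbation trials per direction are few,
#' preferences are taken as the direction/orientation of maximal
#' response (orientation responses fold opposite directions together);
#' argmax ties break toward the lowest angle and are flagged.
#'
#' @param trace Session-long raw rate trace.
#' @param session A `pertflow_session`.
#' @param pref_ori Grating preferred orientation (deg) for `delta_ori`;
#'   optional.
#' @return List (class `perturbation_tuning`): `pert_responses` (per
#'   direction), `ori_responses` (per orientation), `pref_pert_dir`,
#'   `pref_pert_ori`, `delta_ori` (deg in [0, 90], NA without
#'   `pref_ori`), `tie` flag, `n_directions`.
#' @export
perturbation_tuning <- function(trace, session, pref_ori = NULL) {
  trials <- session$trials[session$trials$has_perturbation, ]
  if (length(unique(trials$direction_deg)) < 2)
    stop("perturbation tuning needs perturbation trials in >= 2 directions")
  baseline <- session_baseline_rate(trace, session)
  resp <- vapply(seq_len(nrow(trials)), function(i) {
    w <- epoch_windows(as.list(trials[i, ]))
    window_mean(trace, w$perturbation)
  }, numeric(1)) - baseline
  per_dir <- tapply(resp, factor(trials$direction_deg, levels = DIRECTIONS_DEG),
                    mean)
  oris <- seq(0, 135, by = 45)
  per_ori <- vapply(oris, function(o)
    mean(per_dir[as.character(c(o, o + 180))], na.rm = TRUE), numeric(1))
  names(per_ori) <- oris
  ok_dir <- !is.na(per_dir)
  pref_pert_dir <- DIRECTIONS_DEG[ok_dir][which.max(per_dir[ok_dir])]
  ok_ori <- !is.na(per_ori)
  pref_pert_ori <- oris[ok_ori][which.max(per_ori[ok_ori])]
  tie_ori <- sum(per_ori[ok_ori] == max(per_ori[ok_ori])) > 1
  tie_dir <- sum(per_dir[ok_dir] == max(per_dir[ok_dir])) > 1
  delta_ori <- if (is.null(pref_ori) || is.na(pref_ori)) NA_real_
               else fold_delta_ori(pref_pert_ori, pref_ori)
  structure(list(pert_responses = per_dir, ori_responses = per_ori,
                 pref_pert_dir = pref_pert_dir, pref_pert_ori = pref_pert_ori,
                 delta_ori = delta_ori, tie_ori = tie_ori, tie_dir = tie_dir,
                 tie = tie_ori || tie_dir,
                 n_directions = sum(ok_dir)),
            class = "perturbation_tuning")
}

#' Temporal-frequency tuning from the accelerating-grating protocol
#'
#' Mean rate over the final second of the plateau of every TF-protocol
#' trial, grouped by the trial's plateau TF rounded to the 0.5-cycles/s
#' protocol grid (0, 0.5, ..., 8.5); the preferred TF is the grid value
#' with the maximal mean response, ties toward the lowest TF.
#'
#' @param trace Session-long raw rate trace.
#' @param session A `pertflow_session` with `protocol == "tf"`.
#' @return List (class `tf_tuning`): `tf_values`, `responses`, `n_trials`
#'   per TF, `pref_tf`, `tie` flag.
#' @export
tf_tuning <- function(trace, session) {
  if (!identical(session$protocol, "tf"))
    stop("tf_tuning needs a TF-protocol session")
  trials <- session$trials
  resp <- vapply(seq_len(nrow(trials)), function(i) {
    window_mean(trace, tf_plateau_window(as.list(trials[i, ])))
  }, numeric(1))
  tf_bin <- round(trials$plateau_tf / 0.5) * 0.5
  grid <- sort(unique(tf_bin))
  mresp <- vapply(grid, function(g) mean(resp[tf_bin == g]), numeric(1))
  ntr <- vapply(grid, function(g) sum(tf_bin == g), numeric(1))
  pref <- grid[which.max(mresp)]
  structure(list(tf_values = grid, responses = mresp, n_trials = ntr,
                 pref_tf = pref, tie = sum(mresp == max(mresp)) > 1),
            class = "tf_tuning")
}

#' Tuning analysis of every unit in a session
#'
#' @param session A main-protocol `pertflow_session`.
#' @param rates Optional precomputed [session_rates()].
#' @param response_window_s Grating response window (s).
#' @param alpha Tuning-test significance level.
#' @return List with `results` (per-unit lists: `tuning`, `pert`) and
#'   `table` (per-unit data.frame incl. l_ori, l_dir, pref_ori, pref_dir,
#'   p_ori, p_dir, pref_pert_ori, delta_ori).
#' @export
analyze_tuning <- function(session, rates = NULL, response_window_s = 3.5,
                           alpha = 0.01) {
  if (is.null(rates)) rates <- session_rates(session)
  results <- lapply(seq_along(session$units), function(i) {
    tr <- rates$raw[i, ]
    tun <- unit_tuning(tr, session, response_window_s, alpha)
    pt <- perturbation_tuning(tr, session, pref_ori = tun$pref_ori)
    list(tuning = tun, pert = pt)
  })
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(unit_id = session$units[[i]]$unit_id,
               l_ori = r$tuning$l_ori, l_dir = r$tuning$l_dir,
               pref_ori = r$tuning$pref_ori, pref_dir = r$tuning$pref_dir,
               p_ori = r$tuning$p_ori, p_dir = r$tuning$p_dir,
               ori_tuned = r$tuning$ori_tuned, dir_tuned = r$tuning$dir_tuned,
               pref_pert_ori = r$pert$pref_pert_ori,
               delta_ori = r$pert$delta_ori)
  }))
  list(results = results, table = tab)
}
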