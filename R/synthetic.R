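# Synthetic session generator: inhomogeneous-Poisson units with known
# ground truth (orientation/TF tuning, perturbation modulation, locomotion
# gain), a bout-structured running trace, and class-templated spike
# waveforms. Ground truth is returned as a sidecar, never inside the
# analysis-facing session object.

draw_scalar <- function(n, spec, what, draw) {
  if (is.numeric(spec) && length(spec) == 1L) return(rep(spec, n))
  if (!is.list(spec)) stop("invalid distribution spec for ", what)
  draw(n, spec)
}

draw_lnorm <- function(n, spec, what) {
  draw_scalar(n, spec, what, function(n, s) {
    if (is.null(s$meanlog) || is.null(s$sdlog) || s$sdlog < 0)
      stop("invalid log-normal spec for ", what)
    stats::rlnorm(n, s$meanlog, s$sdlog)
  })
}

draw_gamma <- function(n, spec, what) {
  draw_scalar(n, spec, what, function(n, s) {
    if (s$shape <= 0 || s$rate <= 0) stop("invalid gamma spec for ", what)
    stats::rgamma(n, shape = s$shape, rate = s$rate)
  })
}

draw_beta <- function(n, spec, what) {
  draw_scalar(n, spec, what, function(n, s) {
    if (s$shape1 <= 0 || s$shape2 <= 0) stop("invalid beta spec for ", what)
    stats::rbeta(n, s$shape1, s$shape2)
  })
}

#' Cohort configuration for the synthetic session generator
#'
#' Returns the default study conditions: 160 grating trials (20 per
#' direction), a random 25% carrying the visual-flow perturbation, 8
#' zero-contrast trials, inter-trial intervals uniform on 1-2.5 s, a
#' running trace with bouts crossing the 2 cm/s threshold, and a unit
#' cohort with log-normal baseline/evoked rates, uniform preferred
#' orientations, von-Mises orientation concentration, a bimodal (low/high)
#' preferred-TF mixture, a mixture of positively / negatively / un-
#' modulated perturbation responses, and a locomotion gain on the
#' perturbation response. Any field can be overridden by name; scalar
#' values replace a distribution with a degenerate (fixed) one.
#'
#' @param ... Named overrides of the defaults.
#' @return A config list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_units = 50L,
    n_trials = 160L,
    pert_fraction = 0.25,
    n_blank = 8L,
    tf_repeats = 20L,
    baseline_rate = list(meanlog = log(5), sdlog = 0.5),
    evoked_rate = list(meanlog = log(8), sdlog = 0.4),
    orientation_kappa = list(shape = 2, rate = 1),
    direction_ratio = list(shape1 = 2, shape2 = 2),
    pref_tf = list(p_low = 0.5, low_meanlog = log(0.5), low_sdlog = 0.5,
                   high_meanlog = log(4.5), high_sdlog = 0.35),
    tf_bandwidth = list(meanlog = log(1.5), sdlog = 0.3),
    perturbation_mi = list(p_pos = 0.35, p_neg = 0.30,
                           pos_mean = 1.0, pos_sd = 0.5,
                           neg_mean = 0.5, neg_sd = 0.25),
    couple_tf_mi = TRUE,
    running_gain = list(meanlog = log(1.2), sdlog = 0.15),
    running_pert_gain = list(meanlog = log(2), sdlog = 0.15),
    p_fast = 0.27,
    experience_group = "experienced",
    waveform_noise_sd = 0.02,
    running = list(mean_run_bout = 20, mean_still_bout = 20,
                   run_speed_mean = 8, run_speed_shape = 4,
                   still_speed_max = 0.5, jitter_sd = 0.3, smooth_s = 0.5,
                   p_start_running = 0.5, pert_speed_dip = 0),
    refractory_s = 0
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    for (nm in names(ov)) {
      if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], ov[[nm]])
      else cfg[[nm]] <- ov[[nm]]
    }
  }
  cfg
}

#' Null cohort: no perturbation response, no locomotion gain
#'
#' @param ... Further overrides passed to [cohort_config()].
#' @return A config list with `perturbation_mi = 0`, all gains 1.
#' @export
cohort_null <- function(...) {
  cohort_config(perturbation_mi = 0, running_pert_gain = 1,
                running_gain = 1, couple_tf_mi = FALSE, ...)
}

draw_perturbation_mi <- function(n, spec) {
  if (is.numeric(spec) && length(spec) == 1L) {
    if (spec < -1) stop("perturbation_mi must be >= -1")
    return(rep(spec, n))
  }
  p0 <- 1 - spec$p_pos - spec$p_neg
  if (p0 < 0) stop("perturbation_mi mixture probabilities exceed 1")
  cls <- sample(c(1, -1, 0), n, replace = TRUE,
                prob = c(spec$p_pos, spec$p_neg, p0))
  mi <- numeric(n)
  mi[cls == 1] <- abs(stats::rnorm(sum(cls == 1), spec$pos_mean, spec$pos_sd))
  mi[cls == -1] <- -pmin(abs(stats::rnorm(sum(cls == -1), spec$neg_mean, spec$neg_sd)), 1)
  mi
}

draw_pref_tf <- function(n, spec, mi, couple) {
  if (is.numeric(spec) && length(spec) == 1L) return(rep(spec, n))
  low <- stats::rlnorm(n, spec$low_meanlog, spec$low_sdlog)
  high <- stats::rlnorm(n, spec$high_meanlog, spec$high_sdlog)
  if (couple) {
    # positively modulated units prefer slow/static gratings, negatively
    # modulated ones fast gratings; unmodulated units draw from the mixture
    use_low <- ifelse(mi > 0, TRUE, ifelse(mi < 0, FALSE,
                      stats::runif(n) < spec$p_low))
  } else {
    use_low <- stats::runif(n) < spec$p_low
  }
  ifelse(use_low, low, high)
}

#' Draw ground-truth parameters for a unit cohort
#'
#' @param n Number of units.
#' @param config A [cohort_config()] list.
#' @return data.frame, one row per unit, with the ground-truth fields
#'   (baseline and evoked rates in spikes/s, preferred orientation in
#'   degrees, von-Mises concentration, direction ratio, preferred TF and
#'   bandwidth, target perturbation MI, running gains, waveform class and
#'   experience group).
#' @export
generate_unit_params <- function(n, config = cohort_config()) {
  mi <- draw_perturbation_mi(n, config$perturbation_mi)
  pref_ori <- stats::runif(n, 0, 180)
  data.frame(
    unit_id = seq_len(n),
    baseline_rate = draw_lnorm(n, config$baseline_rate, "baseline_rate"),
    evoked_rate = draw_lnorm(n, config$evoked_rate, "evoked_rate"),
    preferred_orientation = pref_ori,
    preferred_direction = (pref_ori + 180 * stats::rbinom(n, 1, 0.5)) %% 360,
    orientation_kappa = draw_gamma(n, config$orientation_kappa, "orientation_kappa"),
    direction_ratio = draw_beta(n, config$direction_ratio, "direction_ratio"),
    preferred_tf = draw_pref_tf(n, config$pref_tf, mi, isTRUE(config$couple_tf_mi)),
    tf_bandwidth = draw_lnorm(n, config$tf_bandwidth, "tf_bandwidth"),
    perturbation_mi = mi,
    running_gain = draw_lnorm(n, config$running_gain, "running_gain"),
    running_pert_gain = draw_lnorm(n, config$running_pert_gain, "running_pert_gain"),
    waveform_class = ifelse(stats::runif(n) < config$p_fast, "fast", "regular"),
    experience_group = rep(config$experience_group, length.out = n),
    stringsAsFactors = FALSE
  )
}

#' Orientation/direction tuning factor of a synthetic unit
#'
#' Von Mises on twice the angle (orientation tuning) multiplied by a
#' direction asymmetry factor; equals 1 at the preferred direction and
#' `direction_ratio` at the opposite (null) direction.
#'
#' @param direction_deg Stimulus direction(s), degrees.
#' @param unit One ground-truth row (list-like).
#' @return Tuning factor in (0, 1].
#' @export
orientation_factor <- function(direction_deg, unit) {
  th <- direction_deg * pi / 180
  po <- unit$preferred_orientation * pi / 180
  pd <- unit$preferred_direction * pi / 180
  vm <- exp(unit$orientation_kappa * (cos(2 * (th - po)) - 1))
  dr <- unit$direction_ratio
  dirf <- ((1 + dr) + (1 - dr) * cos(th - pd)) / 2
  vm * dirf
}

# TF = 0 (a static grating) is mapped half an octave below the lowest
# tested nonzero TF (0.5 cycles/s) so log-Gaussian tuning is defined there.
TF_STATIC_EQUIV <- 2^(log2(0.5) - 0.5)

#' Temporal-frequency tuning factor of a synthetic unit
#'
#' Log-Gaussian over TF (octave scale), maximum 1 at the preferred TF.
#' TF = 0 is treated as half an octave below the lowest tested TF.
#'
#' @param tf Temporal frequency values, cycles/s (>= 0).
#' @param unit One ground-truth row (list-like).
#' @return Tuning factor in (0, 1].
#' @export
tf_factor <- function(tf, unit) {
  tf_eff <- pmax(tf, TF_STATIC_EQUIV)
  pref_eff <- max(unit$preferred_tf, TF_STATIC_EQUIV)
  exp(-(log2(tf_eff) - log2(pref_eff))^2 / (2 * unit$tf_bandwidth^2))
}

#' Generate a bout-structured running-speed trace
#'
#' Alternating stationary (< 2 cm/s) and running (>= 2 cm/s) bouts with
#' exponentially distributed durations; running-bout speeds are gamma
#' distributed above the threshold, with within-bout jitter and a short
#' box smoothing. Speed is clamped at 0.
#'
#' @param duration_s Trace duration, seconds.
#' @param config Running sub-config (see [cohort_config()]).
#' @return List with `speed` (cm/s, sampled at 60 Hz) and `fs = 60`.
#' @export
generate_running_trace <- function(duration_s, config = cohort_config()$running) {
  fs <- FRAME_RATE
  n <- as.integer(ceiling(duration_s * fs))
  speed <- numeric(n)
  pos <- 1L
  running <- stats::runif(1) < config$p_start_running
  while (pos <= n) {
    mean_dur <- if (running) config$mean_run_bout else config$mean_still_bout
    len <- min(max(1, round(stats::rexp(1, 1 / mean_dur) * fs)), n)
    idx <- pos:min(n, pos + len - 1)
    base <- if (running)
      2 + stats::rgamma(1, shape = config$run_speed_shape,
                        rate = config$run_speed_shape / (config$run_speed_mean - 2))
    else stats::runif(1, 0, config$still_speed_max)
    speed[idx] <- base + stats::rnorm(length(idx), 0, config$jitter_sd)
    pos <- pos + len
    running <- !running
  }
  k <- max(1L, as.integer(round(config$smooth_s * fs)))
  if (k > 1L) speed <- stats::filter(speed, rep(1 / k, k), sides = 2)
  speed <- as.numeric(speed)
  # box filter leaves NAs at the edges; hold the nearest defined value
  if (anyNA(speed)) {
    ok <- which(!is.na(speed))
    speed[seq_len(ok[1] - 1)] <- speed[ok[1]]
    speed[seq((ok[length(ok)] + 1), length.out = length(speed) - ok[length(ok)])] <-
      speed[ok[length(ok)]]
  }
  list(speed = pmax(speed, 0), fs = fs)
}

#' Instantaneous rate profile of a synthetic unit over a session
#'
#' Builds the per-frame rate lambda(t) = baseline + contrast(t) x
#' orientation_tuning(direction) x tf_tuning(tf(t)) x running_gain(t),
#' with the contrast drive normalized to its 0.8 plateau so `evoked_rate`
#' is the plateau evoked rate at the preferred stimulus. During a
#' perturbation epoch the rate steps to
#' lambda_pre x (1 + MI x ori_factor x running_pert_gain(t)), where
#' lambda_pre is the unit's mean rate over the preceding second, so the
#' expected modulation index at the preferred orientation of a stationary
#' animal equals the unit's ground-truth `perturbation_mi`. Rates are
#' clipped at 0.
#'
#' @param unit One ground-truth row (list-like).
#' @param trials Session trial table.
#' @param running Running trace (list with `speed`, `fs`).
#' @param n_frames_total Total session length in frames.
#' @param protocol `"main"` or `"tf"`.
#' @return Numeric vector of per-frame rates, spikes/s.
#' @export
unit_rate_profile <- function(unit, trials, running, n_frames_total,
                              protocol = c("main", "tf")) {
  protocol <- match.arg(protocol)
  p <- main_protocol()
  lam <- rep(unit$baseline_rate, n_frames_total)
  run_on <- running$speed >= 2
  gain <- ifelse(run_on, unit$running_gain, 1)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (isTRUE(tr$blank)) next
    f0 <- as.integer(round(tr$onset_time * FRAME_RATE))
    idx <- f0 + seq_len(tr$n_frames)
    idx <- idx[idx <= n_frames_total]
    nf <- length(idx)
    if (protocol == "main") {
      tl <- build_trial_timeline(tr$direction_deg, has_perturbation = FALSE,
                                 trial_onset_time = tr$onset_time)
      contrast_rel <- tl$contrast_profile[seq_len(nf)] / p$contrast_max
      drive <- contrast_rel * orientation_factor(tr$direction_deg, unit) *
        tf_factor(p$temporal_frequency, unit)
    } else {
      tfp <- tf_trial_profile(as.list(tr))[seq_len(nf)]
      drive <- orientation_factor(tr$direction_deg, unit) * tf_factor(tfp, unit)
    }
    lam[idx] <- unit$baseline_rate + unit$evoked_rate * drive * gain[idx]
    if (protocol == "main" && isTRUE(tr$has_perturbation)) {
      pf <- f0 + tr$pert_onset_frame + seq_len(tr$pert_dur_frames)
      pre <- f0 + tr$pert_onset_frame - 60L + seq_len(60L) - 1L + 1L
      pre <- pre[pre >= 1 & pre <= n_frames_total]
      pf <- pf[pf <= n_frames_total]
      lam_pre <- mean(lam[pre])
      ofac <- orientation_factor(tr$direction_deg, unit)
      rpg <- ifelse(run_on[pf], unit$running_pert_gain, 1)
      lam[pf] <- lam_pre * (1 + unit$perturbation_mi * ofac * rpg)
    }
  }
  pmax(lam, 0)
}

#' Draw spike times from a piecewise-constant rate by thinning
#'
#' Inhomogeneous-Poisson sampling: candidates are drawn homogeneously at
#' the rate maximum and accepted with probability lambda(t)/lambda_max.
#' An optional absolute refractory period is applied by a final pass
#' (off by default).
#'
#' @param lambda Per-frame rate, spikes/s (piecewise constant per frame).
#' @param fs Frame rate of `lambda`, default 60.
#' @param refractory_s Absolute refractory period, seconds (0 disables).
#' @return Sorted spike times in seconds.
#' @export
simulate_inhomogeneous_poisson <- function(lambda, fs = FRAME_RATE,
                                           refractory_s = 0) {
  lmax <- max(lambda)
  if (lmax <= 0) return(numeric(0))
  dur <- length(lambda) / fs
  n_cand <- stats::rpois(1, lmax * dur)
  if (n_cand == 0) return(numeric(0))
  t_cand <- sort(stats::runif(n_cand, 0, dur))
  keep <- stats::runif(n_cand) * lmax < lambda[pmin(floor(t_cand * fs) + 1L, length(lambda))]
  st <- t_cand[keep]
  if (refractory_s > 0 && length(st) > 1) {
    ok <- c(TRUE, diff(st) > refractory_s)
    while (!all(ok)) {  # re-check after removals
      st <- st[ok]
      ok <- c(TRUE, diff(st) > refractory_s)
    }
  }
  st
}

#' Simulate one unit's spike train over a session
#'
#' @inheritParams unit_rate_profile
#' @return Sorted spike times, seconds.
#' @export
simulate_spikes <- function(unit, trials, running, n_frames_total,
                            protocol = "main", refractory_s = 0) {
  lam <- unit_rate_profile(unit, trials, running, n_frames_total, protocol)
  simulate_inhomogeneous_poisson(lam, refractory_s = refractory_s)
}

#' Generate a mean spike waveform from a class template
#'
#' Difference-of-Gaussians templates: a dominant trough followed by a
#' positive after-peak at the class trough-to-peak delay (0.83 ms for
#' regular-spiking, 0.37 ms for fast-spiking units), plus optional white
#' noise.
#'
#' @param class `"regular"` or `"fast"`.
#' @param fs Sampling rate, Hz (default 30 kHz).
#' @param noise_sd White-noise SD relative to trough amplitude (1).
#' @param duration_ms Template length, ms.
#' @return List with `waveform` (numeric) and `fs`.
#' @export
generate_waveform <- function(class = c("regular", "fast"), fs = 30000,
                              noise_sd = 0, duration_ms = 4) {
  class <- match.arg(class)
  t_ms <- seq(0, duration_ms, by = 1000 / fs)
  pars <- if (class == "regular")
    list(ttp = 0.83, trough_sd = 0.15, peak_sd = 0.35, peak_amp = 0.35)
  else
    list(ttp = 0.37, trough_sd = 0.10, peak_sd = 0.16, peak_amp = 0.35)
  t_trough <- 1.2
  w <- -exp(-(t_ms - t_trough)^2 / (2 * pars$trough_sd^2)) +
    pars$peak_amp * exp(-(t_ms - t_trough - pars$ttp)^2 / (2 * pars$peak_sd^2))
  if (noise_sd > 0) w <- w + stats::rnorm(length(w), 0, noise_sd)
  list(waveform = w, fs = fs)
}

build_main_trials <- function(config) {
  n <- config$n_trials
  dirs <- seq(0, 315, by = 45)
  per_dir <- n %/% length(dirs)
  direction <- c(rep(dirs, per_dir), sample(dirs, n - per_dir * length(dirs)))
  direction <- sample(direction)
  n_pert <- as.integer(round(config$pert_fraction * n))
  pert <- rep(FALSE, n)
  pert[sample.int(n, n_pert)] <- TRUE
  trials <- data.frame(direction_deg = direction, blank = FALSE,
                       has_perturbation = pert)
  if (config$n_blank > 0) {
    blanks <- data.frame(
      direction_deg = rep(dirs, length.out = config$n_blank),
      blank = TRUE, has_perturbation = FALSE)
    trials <- rbind(trials, blanks)
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  }
  m <- nrow(trials)
  p <- main_protocol()
  trials$n_frames <- p$n_frames
  # perturbation windows: real for perturbation trials, virtual (same
  # distribution) for non-perturbation grating trials
  trials$pert_onset_frame <- NA_integer_
  trials$pert_dur_frames <- NA_integer_
  grating <- !trials$blank
  trials$pert_onset_frame[grating] <-
    sample(p$pert_onset_range[1]:p$pert_onset_range[2], sum(grating), replace = TRUE)
  trials$pert_dur_frames[grating] <-
    sample(p$pert_duration_range[1]:p$pert_duration_range[2], sum(grating), replace = TRUE)
  trials$window_virtual <- grating & !trials$has_perturbation
  iti <- stats::runif(m, p$iti_range[1], p$iti_range[2])
  onset_frames <- cumsum(c(round(iti[1] * FRAME_RATE),
                           trials$n_frames[-m] + round(iti[-1] * FRAME_RATE)))
  trials$onset_time <- onset_frames / FRAME_RATE
  trials$trial_id <- seq_len(m)
  rownames(trials) <- NULL
  trials[, c("trial_id", "onset_time", "direction_deg", "blank",
             "has_perturbation", "pert_onset_frame", "pert_dur_frames",
             "window_virtual", "n_frames")]
}

build_tf_trials <- function(config) {
  tr <- build_tf_protocol(config$tf_repeats)
  m <- nrow(tr)
  p <- main_protocol()
  iti <- stats::runif(m, p$iti_range[1], p$iti_range[2])
  onset_frames <- cumsum(c(round(iti[1] * FRAME_RATE),
                           tr$n_frames[-m] + round(iti[-1] * FRAME_RATE)))
  tr$onset_time <- onset_frames / FRAME_RATE
  tr$direction_deg <- 0
  tr$blank <- FALSE
  tr$has_perturbation <- FALSE
  tr$trial_id <- seq_len(m)
  tr
}

#' Generate a complete synthetic session with a ground-truth sidecar
#'
#' Deterministic given `seed`. The returned `session` holds only the
#' analysis-facing data (spike times, waveforms, trial table, running
#' trace); the generating parameters live in the separate `ground_truth`
#' data frame.
#'
#' @param config A [cohort_config()] list.
#' @param seed Integer RNG seed.
#' @param protocol `"main"` (perturbation paradigm) or `"tf"`
#'   (accelerating-grating TF protocol).
#' @param unit_params Optional pre-drawn ground truth (to simulate the
#'   same cohort under a second protocol); default draws a new cohort.
#' @return List with `session` (class `pertflow_session`) and
#'   `ground_truth`.
#' @export
generate_session <- function(config = cohort_config(), seed = 1,
                             protocol = c("main", "tf"), unit_params = NULL) {
  protocol <- match.arg(protocol)
  set.seed(seed)
  trials <- if (protocol == "main") build_main_trials(config) else build_tf_trials(config)
  last <- trials[nrow(trials), ]
  duration <- last$onset_time + last$n_frames / FRAME_RATE + 1
  n_frames_total <- as.integer(ceiling(duration * FRAME_RATE))
  running <- generate_running_trace(n_frames_total / FRAME_RATE, config$running)
  # optional behavioral coupling: the animal slows during perturbations
  dip <- config$running$pert_speed_dip
  if (!is.null(dip) && dip > 0 && protocol == "main") {
    for (i in which(trials$has_perturbation)) {
      f0 <- as.integer(round(trials$onset_time[i] * FRAME_RATE))
      idx <- f0 + trials$pert_onset_frame[i] + seq_len(trials$pert_dur_frames[i])
      idx <- idx[idx <= length(running$speed)]
      running$speed[idx] <- pmax(running$speed[idx] - dip, 0)
    }
  }
  gt <- if (is.null(unit_params)) generate_unit_params(config$n_units, config) else unit_params
  units <- lapply(seq_len(nrow(gt)), function(i) {
    u <- as.list(gt[i, ])
    wf <- generate_waveform(u$waveform_class, noise_sd = config$waveform_noise_sd)
    list(
      unit_id = u$unit_id,
      spike_times = simulate_spikes(u, trials, running, n_frames_total,
                                    protocol = protocol,
                                    refractory_s = config$refractory_s),
      waveform = wf$waveform,
      waveform_fs = wf$fs
    )
  })
  session <- structure(list(
    units = units,
    trials = trials,
    running = running,
    duration = n_frames_total / FRAME_RATE,
    protocol = protocol,
    meta = list(n_units = nrow(gt), seed = seed,
                experience_group = config$experience_group)
  ), class = "pertflow_session")
  list(session = session, ground_truth = gt)
}

#' @export
print.pertflow_session <- function(x, ...) {
  cat(sprintf("<pertflow_session: %d units, %d trials (%s protocol), %.0f s>\n",
              length(x$units), nrow(x$trials), x$protocol, x$duration))
  invisible(x)
}

#' Serialize a session bundle to JSON
#'
#' Plain-text session export (units with spike times and waveforms, the
#' trial table, and the running trace), readable back with
#' [read_session_json()].
#'
#' @param session A `pertflow_session`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_session_json <- function(session, path) {
  obj <- unclass(session)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$trials <- as.data.frame(obj$trials)
  obj$units <- lapply(seq_along(obj$units$unit_id), function(i) {
    list(unit_id = obj$units$unit_id[[i]],
         spike_times = as.numeric(obj$units$spike_times[[i]]),
         waveform = as.numeric(obj$units$waveform[[i]]),
         waveform_fs = obj$units$waveform_fs[[i]])
  })
  structure(obj, class = "pertflow_session")
}
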