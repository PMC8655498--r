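# Frame-accurate stimulus protocol for the drifting-grating perturbation
# paradigm. Conventions used throughout the package:
#   * frames are 0-based, displayed at 60 frames/s;
#   * time intervals are half-open [start, end) in session-clock seconds;
#   * frame f of a trial starting at t0 covers [t0 + f/60, t0 + (f+1)/60).

FRAME_RATE <- 60

#' Main-protocol constants
#'
#' Frame counts and stimulus parameters of the main drifting-grating trial:
#' 440 frames at 60 Hz (~7.33 s), contrast ramping 0 -> 0.8 over the first
#' 240 frames, holding 0.8 for 100 frames, then falling back to 0 over 100
#' frames; spatial frequency 0.04 cycles/degree and temporal frequency
#' 3 cycles/s. The perturbation (temporal frequency forced to 0) starts
#' 30-40 frames after the contrast reaches its plateau and lasts 60-70
#' frames.
#'
#' @return Named list of protocol constants.
#' @export
main_protocol <- function() {
  list(
    frame_rate = FRAME_RATE,
    n_frames = 440L,
    ramp_frames = 240L,
    hold_frames = 100L,
    fall_frames = 100L,
    contrast_max = 0.8,
    temporal_frequency = 3,
    spatial_frequency = 0.04,
    pert_onset_range = c(270L, 280L),   # ramp_frames + [30, 40]
    pert_duration_range = c(60L, 70L),
    iti_range = c(1, 2.5)
  )
}

#' Build the frame-accurate timeline of one grating trial
#'
#' Constructs the per-frame contrast and temporal-frequency profiles of a
#' single trial of the main protocol. When `has_perturbation` is `TRUE`, a
#' perturbation window (TF set to 0) is drawn uniformly: onset on frames
#' 270-280 (30-40 frames after the contrast plateau is reached), duration
#' 60-70 frames. Blank (zero-contrast) trials carry the same timing grid
#' with contrast identically 0.
#'
#' @param direction_deg Grating drift direction, one of 0, 45, ..., 315.
#' @param has_perturbation Logical; include a visual-flow perturbation?
#' @param blank Logical; zero-contrast trial (used for baseline estimation).
#' @param trial_onset_time Trial start in session-clock seconds.
#' @return An object of class `trial_timeline`: a list with the per-frame
#'   `contrast_profile` and `tf_profile`, the perturbation window in frames
#'   (if any), and timing fields.
#' @export
build_trial_timeline <- function(direction_deg, has_perturbation = FALSE,
                                 blank = FALSE, trial_onset_time = 0) {
  p <- main_protocol()
  if (length(direction_deg) != 1L || !(direction_deg %in% seq(0, 315, by = 45)))
    stop("direction_deg must be one of 0, 45, ..., 315 (got ",
         direction_deg, ")")
  f <- seq_len(p$n_frames) - 1L  # 0-based frame index
  contrast <- numeric(p$n_frames)
  ramp_end <- p$ramp_frames
  hold_end <- ramp_end + p$hold_frames
  contrast[f < ramp_end] <- p$contrast_max * (f[f < ramp_end] + 1) / p$ramp_frames
  contrast[f >= ramp_end & f < hold_end] <- p$contrast_max
  idx_fall <- f >= hold_end
  contrast[idx_fall] <- p$contrast_max * (p$n_frames - 1 - f[idx_fall]) / p$fall_frames
  if (blank) contrast[] <- 0

  tf <- rep(p$temporal_frequency, p$n_frames)
  onset <- dur <- NA_integer_
  if (isTRUE(has_perturbation)) {
    onset <- sample(p$pert_onset_range[1]:p$pert_onset_range[2], 1L)
    dur <- sample(p$pert_duration_range[1]:p$pert_duration_range[2], 1L)
    tf[f >= onset & f < onset + dur] <- 0
  }
  structure(list(
    direction_deg = direction_deg,
    contrast_profile = contrast,
    tf_profile = tf,
    spatial_frequency = p$spatial_frequency,
    has_perturbation = isTRUE(has_perturbation),
    blank = isTRUE(blank),
    perturbation_onset_frame = onset,
    perturbation_duration_frames = dur,
    trial_onset_time = trial_onset_time,
    n_frames = p$n_frames
  ), class = "trial_timeline")
}

#' Sample a virtual perturbation window
#'
#' Non-perturbation trials receive a "virtual" perturbation window drawn
#' from the same onset/duration distribution as real ones, so that the
#' trial classifier has matched feature windows on both trial types.
#'
#' @return List with integer `onset` (frames) and `duration` (frames).
#' @export
sample_virtual_window <- function() {
  p <- main_protocol()
  list(onset = sample(p$pert_onset_range[1]:p$pert_onset_range[2], 1L),
       duration = sample(p$pert_duration_range[1]:p$pert_duration_range[2], 1L))
}

#' Epoch windows of a trial
#'
#' Converts a trial's perturbation window into the half-open analysis
#' epochs, in session-clock seconds: `perturbation` = [t_on, t_off),
#' `pre_perturbation` = the 1 s immediately preceding it, and
#' `stimulus_response` = the first `response_window_s` seconds of the trial
#' (used for grating tuning). For trials without a real perturbation a
#' virtual window is sampled (or taken from the timeline if already
#' assigned) and flagged `virtual = TRUE`.
#'
#' @param trial A `trial_timeline`, or any list with the same fields
#'   (e.g. a row of a session's trial table turned into a list).
#' @param response_window_s Grating response window length, default 3.5 s.
#' @return List of numeric `c(start, end)` intervals plus a `virtual` flag.
#' @export
epoch_windows <- function(trial, response_window_s = 3.5) {
  # accept both a trial_timeline and a row of a session trial table
  t0 <- if (!is.null(trial$trial_onset_time)) trial$trial_onset_time else trial$onset_time
  onset <- if (!is.null(trial$perturbation_onset_frame)) trial$perturbation_onset_frame
           else trial$pert_onset_frame
  dur <- if (!is.null(trial$perturbation_duration_frames)) trial$perturbation_duration_frames
         else trial$pert_dur_frames
  virtual <- !isTRUE(trial$has_perturbation)
  if (is.null(onset) || is.na(onset)) {
    vw <- sample_virtual_window()
    onset <- vw$onset; dur <- vw$duration
  }
  t_on <- t0 + onset / FRAME_RATE
  t_off <- t0 + (onset + dur) / FRAME_RATE
  list(
    pre_perturbation = c(t_on - 1, t_on),
    perturbation = c(t_on, t_off),
    stimulus_response = c(t0, t0 + response_window_s),
    trial_window = c(t0, t0 + trial$n_frames / FRAME_RATE),
    virtual = virtual
  )
}

#' Build the accelerating-grating temporal-frequency protocol
#'
#' Each trial starts with a grating drifting at 1.5, 3 or 6 cycles/s for
#' 1 s, then accelerates at one of -3,-2,...,3 cycles/s^2 for 0.5 or 1 s,
#' then holds the resulting plateau TF for 1.5-2 s. The plateau TF is
#' clamped at 0 (a static grating). All 21 (initial TF, acceleration)
#' combinations appear exactly `n_repeats` times, in randomized order.
#'
#' @param n_repeats Number of repeats per combination (>= 1).
#' @return data.frame with one row per trial: `initial_tf`, `acceleration`,
#'   `acceleration_duration` (s), `plateau_tf`, `plateau_frames`,
#'   `n_frames`.
#' @export
build_tf_protocol <- function(n_repeats = 20L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  combos <- expand.grid(initial_tf = c(1.5, 3, 6), acceleration = -3:3)
  tr <- combos[rep(seq_len(nrow(combos)), each = n_repeats), ]
  tr <- tr[sample.int(nrow(tr)), , drop = FALSE]
  tr$acceleration_duration <- sample(c(0.5, 1), nrow(tr), replace = TRUE)
  tr$plateau_tf <- pmax(0, tr$initial_tf + tr$acceleration * tr$acceleration_duration)
  tr$plateau_frames <- sample(90:120, nrow(tr), replace = TRUE)
  tr$n_frames <- as.integer(60 + tr$acceleration_duration * FRAME_RATE + tr$plateau_frames)
  rownames(tr) <- NULL
  tr
}

#' Per-frame temporal-frequency profile of a TF-protocol trial
#'
#' @param trial One row of [build_tf_protocol()] output (as list or
#'   one-row data.frame).
#' @return Numeric vector of per-frame TF (cycles/s), clamped at 0.
#' @export
tf_trial_profile <- function(trial) {
  accel_frames <- as.integer(round(trial$acceleration_duration * FRAME_RATE))
  f <- seq_len(trial$n_frames) - 1L
  tf <- numeric(trial$n_frames)
  tf[f < 60] <- trial$initial_tf
  idx <- f >= 60 & f < 60 + accel_frames
  tf[idx] <- trial$initial_tf + trial$acceleration * (f[idx] - 60 + 1) / FRAME_RATE
  tf[f >= 60 + accel_frames] <- trial$initial_tf + trial$acceleration * trial$acceleration_duration
  pmax(0, tf)
}

#' Plateau window of a TF-protocol trial
#'
#' The final 1 s of the constant-TF plateau, used for the speed tuning
#' curve.
#'
#' @param trial One row of [build_tf_protocol()] (list-like) with a
#'   `trial_onset_time` field.
#' @return Numeric `c(start, end)` in session seconds.
#' @export
tf_plateau_window <- function(trial) {
  t0 <- if (!is.null(trial$trial_onset_time)) trial$trial_onset_time else trial$onset_time
  t_end <- t0 + trial$n_frames / FRAME_RATE
  c(t_end - 1, t_end)
}

#' Write a protocol trial table as JSON and a per-frame CSV
#'
#' @param trials Trial table (data.frame) of a session.
#' @param json_path,csv_path Output paths; `NULL` skips that output.
#'   The CSV holds per-frame contrast/TF/direction for main-protocol
#'   trials.
#' @return Invisibly, the trial table.
#' @export
write_protocol <- function(trials, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(trials, json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (!is.null(csv_path)) {
    rows <- lapply(seq_len(nrow(trials)), function(i) {
      tr <- as.list(trials[i, ])
      tl <- build_trial_timeline(tr$direction_deg,
                                 has_perturbation = isTRUE(tr$has_perturbation),
                                 blank = isTRUE(tr$blank),
                                 trial_onset_time = tr$onset_time)
      if (isTRUE(tr$has_perturbation)) {
        f <- seq_len(tl$n_frames) - 1L
        tl$tf_profile <- rep(main_protocol()$temporal_frequency, tl$n_frames)
        tl$tf_profile[f >= tr$pert_onset_frame &
                      f < tr$pert_onset_frame + tr$pert_duration_frames] <- 0
      }
      data.frame(trial = i, frame = seq_len(tl$n_frames) - 1L,
                 contrast = tl$contrast_profile, tf = tl$tf_profile,
                 direction = tr$direction_deg)
    })
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  invisible(trials)
}
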