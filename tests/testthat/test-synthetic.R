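test_that("sessions are deterministic given the seed", {
  a <- generate_session(cohort_config(n_units = 2), seed = 7)
  b <- generate_session(cohort_config(n_units = 2), seed = 7)
  expect_identical(a, b)
  c <- generate_session(cohort_config(n_units = 2), seed = 8)
  expect_false(identical(a$session$units[[1]]$spike_times,
                         c$session$units[[1]]$spike_times))
})

test_that("trial bookkeeping matches the protocol fractions", {
  g <- generate_session(cohort_config(n_units = 1, n_trials = 160), seed = 9)
  tr <- g$session$trials
  grating <- tr[!tr$blank, ]
  expect_equal(nrow(grating), 160)
  expect_equal(sum(grating$has_perturbation), 40)  # exactly 25%
  expect_equal(as.integer(table(grating$direction_deg)), rep(20L, 8))
  expect_equal(sum(tr$blank), 8)
  # ITIs within [1, 2.5] s (frame-rounded)
  ends <- tr$onset_time + tr$n_frames / 60
  itis <- tr$onset_time[-1] - ends[-nrow(tr)]
  expect_true(all(itis >= 1 - 1 / 60 & itis <= 2.5 + 1 / 60))
  # virtual windows on all non-perturbation grating trials, in bounds
  virt <- grating[!grating$has_perturbation, ]
  expect_true(all(virt$window_virtual))
  expect_true(all(virt$pert_onset_frame >= 270 & virt$pert_onset_frame <= 280))
  expect_true(all(virt$pert_dur_frames >= 60 & virt$pert_dur_frames <= 70))
})

test_that("cohort draws respect their distributions and validation", {
  set.seed(13)
  gt <- generate_unit_params(1000, cohort_config())
  expect_true(all(gt$baseline_rate >= 0))
  expect_true(all(gt$orientation_kappa >= 0))
  expect_true(all(gt$running_gain > 0))
  expect_true(all(gt$perturbation_mi >= -1))
  # preferred orientations uniform on [0, 180)
  h <- table(cut(gt$preferred_orientation, breaks = seq(0, 180, by = 22.5)))
  expect_gt(chisq.test(h)$p.value, 0.01)
  # degenerate configs
  gt0 <- generate_unit_params(50, cohort_null())
  expect_true(all(gt0$perturbation_mi == 0))
  expect_error(generate_unit_params(5, cohort_config(baseline_rate = list(meanlog = 0, sdlog = -1))),
               "log-normal")
  expect_error(cohort_config(nonsense = 1), "unknown config")
})

test_that("running traces are nonnegative and yield both states reliably", {
  set.seed(14)
  ok <- 0L
  for (s in 1:60) {
    g <- generate_session(cohort_config(n_units = 0), seed = 4000 + s)
    expect_true(all(g$session$running$speed >= 0))
    sp <- split_trials_by_running(g$session)
    if (length(sp$running) >= 4 && length(sp$stationary) >= 4) ok <- ok + 1L
  }
  expect_gte(ok / 60, 0.95)
  # degenerate configs
  cfg <- cohort_config()$running
  cfg$mean_run_bout <- 1e-9; cfg$mean_still_bout <- 1e9; cfg$p_start_running <- 0
  tr <- generate_running_trace(100, cfg)
  expect_true(all(tr$speed < 2))
  cfg2 <- cohort_config()$running
  cfg2$mean_run_bout <- 1e9; cfg2$p_start_running <- 1
  cfg2$run_speed_mean <- 10; cfg2$jitter_sd <- 0; cfg2$still_speed_max <- 0
  tr2 <- generate_running_trace(100, cfg2)
  expect_true(all(tr2$speed >= 2))
})

test_that("Poisson thinning realizes the target rate profile", {
  set.seed(15)
  # constant rate: count within 3 sigma of lambda x T
  st <- simulate_inhomogeneous_poisson(rep(5, 100 * 60))
  expect_lt(abs(length(st) - 500), 3 * sqrt(500))
  expect_false(is.unsorted(st))
  # zero rate
  expect_length(simulate_inhomogeneous_poisson(rep(0, 600)), 0)
  # segment-wise empirical rates track an inhomogeneous profile
  lam <- rep(c(2, 10, 4, 20, 1), each = 40 * 60)  # five 40-s segments
  st2 <- simulate_inhomogeneous_poisson(lam)
  seg <- findInterval(st2, (0:4) * 40, rightmost.closed = FALSE)
  for (k in 1:5) {
    expected <- c(2, 10, 4, 20, 1)[k] * 40
    expect_lt(abs(sum(seg == k) - expected), 4 * sqrt(expected))
  }
  # refractory option removes short ISIs
  st3 <- simulate_inhomogeneous_poisson(rep(50, 60 * 60), refractory_s = 0.003)
  expect_true(all(diff(st3) > 0.003))
})

test_that("MI = -1 silences the perturbation epochs of an untuned unit", {
  g <- generate_session(recovery_config(-1, n_units = 1), seed = 16)
  st <- g$session$units[[1]]$spike_times
  pt <- g$session$trials[g$session$trials$has_perturbation, ]
  for (i in seq_len(nrow(pt))) {
    w <- epoch_windows(as.list(pt[i, ]))
    expect_equal(sum(st >= w$perturbation[1] & st < w$perturbation[2]), 0)
  }
})

test_that("simulated PSTH matches the analytic rate within Poisson bands", {
  # one untuned unit, repeated draws from its lambda profile: the expected
  # count over any window is the integral of lambda
  g <- generate_session(cohort_config(n_units = 1, orientation_kappa = 0,
                                      direction_ratio = 1, running_gain = 1,
                                      running_pert_gain = 1,
                                      perturbation_mi = 0.5), seed = 17)
  s <- g$session
  u <- as.list(g$ground_truth[1, ])
  nf <- as.integer(round(s$duration * 60))
  lam <- unit_rate_profile(u, s$trials, s$running, nf)
  set.seed(18)
  segs <- seq(0, floor(s$duration) - 10, by = 10)[1:50]
  n_ok <- 0L
  st <- simulate_inhomogeneous_poisson(lam)
  for (a in segs) {
    expected <- sum(lam[(a * 60 + 1):((a + 10) * 60)]) / 60
    obs <- sum(st >= a & st < a + 10)
    if (abs(obs - expected) <= 3.5 * sqrt(max(expected, 1))) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 48)
})

test_that("waveform templates hit the class trough-to-peak delays", {
  wr <- generate_waveform("regular")
  wf <- generate_waveform("fast")
  expect_equal(trough_to_peak(wr$waveform, wr$fs)$ttp_ms, 0.83, tolerance = 0.05)
  expect_equal(trough_to_peak(wf$waveform, wf$fs)$ttp_ms, 0.37, tolerance = 0.05)
  # single dominant trough, peak after trough
  r <- trough_to_peak(wr$waveform, wr$fs)
  expect_gt(r$peak_index, r$trough_index)
  expect_false(r$flagged)
})

test_that("ground truth stays in the sidecar, not in the session", {
  g <- small_session()
  gt_fields <- c("perturbation_mi", "running_gain", "running_pert_gain",
                 "preferred_orientation", "orientation_kappa", "preferred_tf",
                 "baseline_rate", "evoked_rate")
  leaked <- function(x) any(gt_fields %in% names(x))
  expect_false(leaked(g$session))
  expect_false(leaked(g$session$trials))
  expect_false(any(vapply(g$session$units, leaked, logical(1))))
  expect_true(all(gt_fields %in% names(g$ground_truth)))
})

test_that("session JSON round-trips the analysis-facing bundle", {
  g <- generate_session(cohort_config(n_units = 2, n_trials = 16, n_blank = 2),
                        seed = 19)
  p <- withr::local_tempfile(fileext = ".json")
  write_session_json(g$session, p)
  back <- read_session_json(p)
  expect_equal(back$units[[1]]$spike_times, g$session$units[[1]]$spike_times)
  expect_equal(back$trials$onset_time, g$session$trials$onset_time)
  expect_equal(back$running$speed, g$session$running$speed)
})
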