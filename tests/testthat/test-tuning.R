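test_that("vector-sum selectivity matches hand-computed and brute-force values", {
  R_flat <- rep(2, 8)
  o <- orientation_selectivity(R_flat)
  expect_equal(o$l_ori, 0)
  d <- direction_selectivity(R_flat)
  expect_equal(d$l_dir, 0)
  # single active direction
  R1 <- c(0, 0, 5, 0, 0, 0, 0, 0)  # 90 deg
  expect_equal(orientation_selectivity(R1)$l_ori, 1)
  expect_equal(orientation_selectivity(R1)$pref_ori, 90)
  expect_equal(direction_selectivity(R1)$l_dir, 1)
  expect_equal(direction_selectivity(R1)$pref_dir, 90)
  # R(0)=2, R(90)=1: |2 e^0 + 1 e^{2i*90deg}| / 3 = 1/3, pref 0
  R2 <- c(2, 0, 1, 0, 0, 0, 0, 0)
  o2 <- orientation_selectivity(R2)
  expect_equal(o2$l_ori, 1 / 3)
  expect_equal(o2$pref_ori, 0)
  # two equal opposite directions cancel in direction space
  R3 <- c(3, 0, 0, 0, 3, 0, 0, 0)
  expect_equal(direction_selectivity(R3)$l_dir, 0)
  expect_equal(orientation_selectivity(R3)$l_ori, 1)
  # brute-force complex-sum oracle on random nonnegative responses
  set.seed(40)
  th <- seq(0, 315, by = 45) * pi / 180
  for (i in 1:50) {
    R <- runif(8, 0, 10)
    zo <- sum(R * exp(2i * th)); zd <- sum(R * exp(1i * th))
    expect_equal(orientation_selectivity(R)$l_ori, Mod(zo) / sum(R), tolerance = 1e-12)
    expect_equal(direction_selectivity(R)$l_dir, Mod(zd) / sum(R), tolerance = 1e-12)
    # invariance under positive rescaling
    expect_equal(orientation_selectivity(5 * R)$l_ori,
                 orientation_selectivity(R)$l_ori, tolerance = 1e-12)
  }
  # all-zero rectified responses are untunable
  expect_true(orientation_selectivity(rep(-1, 8))$untunable)
})

test_that("Hotelling's T2 handles significance, degeneracy, and null calibration", {
  dirs <- rep(seq(0, 315, by = 45), 8)
  # identical nonzero trial vectors: zero variance, nonzero mean
  ht <- hotelling_t2_orientation(rep(5, 16), rep(c(0, 180), 8))
  expect_equal(ht$p, 0)
  expect_true(ht$degenerate)
  expect_error(hotelling_t2_orientation(c(1, 2), c(0, 90)), "at least 3")
  # strong tuning: tiny p
  set.seed(41)
  resp <- 5 * cos(2 * dirs * pi / 180) + rnorm(64, 0, 0.5)
  expect_lt(hotelling_t2_orientation(resp, dirs)$p, 1e-6)
  # null calibration: isotropic mean-zero responses give uniform p-values
  p_null <- replicate(400, {
    hotelling_t2_orientation(rnorm(64), sample(dirs))$p
  })
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)
  expect_lt(mean(p_null < 0.01), 0.03)
})

test_that("the direction dot-product test separates directional from symmetric tuning", {
  dirs <- rep(seq(0, 315, by = 45), 10)
  set.seed(42)
  # consistently directional responses: projections positive on every trial
  resp_dir <- 10 * cos((dirs - 90) * pi / 180) + rnorm(80, 0, 0.2)
  expect_lt(direction_dot_product_test(resp_dir, dirs, 90)$p, 1e-8)
  # orientation-symmetric responses: projections cancel in expectation
  p_sym <- replicate(200, {
    resp <- 5 * abs(cos(2 * dirs * pi / 180)) + rnorm(80, 0, 1)
    direction_dot_product_test(resp, dirs, 0)$p
  })
  expect_lt(mean(p_sym < 0.01), 0.05)
  expect_gt(mean(p_sym), 0.3); expect_lt(mean(p_sym), 0.7)
  # label-shuffle false positives controlled at the 1% level
  resp_tuned <- 5 * cos((dirs - 90) * pi / 180) + rnorm(80, 0, 1)
  p_shuf <- replicate(400, {
    ds <- sample(dirs)
    pd <- direction_selectivity(tapply(resp_tuned, factor(ds, levels = seq(0, 315, 45)),
                                       mean))$pref_dir
    direction_dot_product_test(resp_tuned, ds, pd)$p
  })
  expect_lte(mean(p_shuf < 0.01), 0.03)
  expect_error(direction_dot_product_test(c(1, 2), c(0, 90), 0), "at least 3")
})

test_that("grating tuning recovers simulated orientation preferences", {
  # kappa >= 2 cohort, 20 trials/direction: preferred orientation within
  # +/- 22.5 degrees for >= 90% of units
  cfg <- cohort_config(n_units = 10, orientation_kappa = 2.5,
                       baseline_rate = 6, evoked_rate = 10, pref_tf = 3,
                       running_gain = 1, running_pert_gain = 1,
                       perturbation_mi = 0.5, couple_tf_mi = FALSE)
  hits <- tuned <- 0L
  for (s in 1:3) {
    g <- generate_session(cfg, seed = 700 + s)
    rates <- session_rates(g$session)
    tun <- analyze_tuning(g$session, rates)
    d <- mapply(function(est, gt) pertflow:::fold_delta_ori(est, gt) <= 22.5,
                tun$table$pref_ori, g$ground_truth$preferred_orientation)
    hits <- hits + sum(d); tuned <- tuned + sum(tun$table$ori_tuned)
  }
  expect_gte(hits / 30, 0.9)
  expect_gte(tuned / 30, 0.9)  # Hotelling flags these strongly tuned units
})

test_that("simulated direction responses track the analytic tuning profile", {
  cfg <- cohort_config(n_units = 1, orientation_kappa = 1.5,
                       baseline_rate = 5, evoked_rate = 12, running_gain = 1,
                       running_pert_gain = 1, perturbation_mi = 0,
                       pref_tf = 3, couple_tf_mi = FALSE)
  g <- generate_session(cfg, seed = 44)
  rates <- session_rates(g$session)
  dr <- direction_responses(rates$raw[1, ], g$session)
  u <- as.list(g$ground_truth[1, ])
  # analytic expectation: evoked x mean contrast over the 3.5-s window x tuning
  tl <- build_trial_timeline(0)
  mean_contrast <- mean(tl$contrast_profile[1:210]) / 0.8
  expected <- u$evoked_rate * mean_contrast *
    orientation_factor(seq(0, 315, 45), u) * tf_factor(3, u)
  # each direction mean over 20 trials: allow 4 sigma Poisson-level noise
  sem <- sqrt((u$baseline_rate + expected) / (20 * 3.5))
  expect_true(all(abs(dr$responses - expected) < 4 * sem + 0.3))
})

test_that("perturbation tuning folds orientations and reports delta-ori", {
  g0 <- generate_session(cohort_config(n_units = 0), seed = 45)
  s <- g0$session
  nf <- as.integer(round(s$duration * 60))
  # synthetic trace: responds during perturbation only on 90/270-deg trials
  trace <- rep(1, nf)
  pt <- s$trials[s$trials$has_perturbation, ]
  for (i in seq_len(nrow(pt))) {
    if (pt$direction_deg[i] %in% c(90, 270)) {
      w <- epoch_windows(as.list(pt[i, ]))
      idx <- pertflow:::window_bins(w$perturbation, 60, 0, nf)
      trace[idx] <- 11
    }
  }
  ptun <- perturbation_tuning(trace, s, pref_ori = 0)
  expect_equal(ptun$pref_pert_ori, 90)
  expect_equal(ptun$delta_ori, 90)
  expect_false(ptun$tie_ori)
  # flat perturbation response: tie broken toward the lowest angle, flagged
  ptun2 <- perturbation_tuning(rep(1, nf), s, pref_ori = 45)
  expect_true(ptun2$tie)
  expect_equal(ptun2$pref_pert_ori, 0)
})

test_that("delta-ori folding maps into [0, 90]", {
  expect_equal(pertflow:::fold_delta_ori(170, 10), 20)
  expect_equal(pertflow:::fold_delta_ori(0, 90), 90)
  expect_equal(pertflow:::fold_delta_ori(135, 0), 45)
  set.seed(46)
  a <- runif(100, 0, 180); b <- runif(100, 0, 180)
  d <- pertflow:::fold_delta_ori(a, b)
  expect_true(all(d >= 0 & d <= 90))
})

test_that("TF tuning recovers grid-valued preferred temporal frequencies", {
  prefs <- c(0, 1, 3, 5)
  cfg <- cohort_config(n_units = 4, orientation_kappa = 0, direction_ratio = 1,
                       baseline_rate = 4, evoked_rate = 15, tf_bandwidth = 0.8,
                       running_gain = 1, running_pert_gain = 1,
                       perturbation_mi = 0, couple_tf_mi = FALSE)
  g <- generate_session(cfg, seed = 47, protocol = "tf")
  g$ground_truth$preferred_tf <- prefs
  # re-simulate with the pinned preferences
  g2 <- generate_session(cfg, seed = 48, protocol = "tf",
                         unit_params = g$ground_truth)
  rates <- session_rates(g2$session)
  for (i in seq_along(prefs)) {
    tf <- tf_tuning(rates$raw[i, ], g2$session)
    expect_lte(abs(tf$pref_tf - prefs[i]), 0.5)
    expect_true(tf$pref_tf %in% tf$tf_values)
  }
  # flat response: lowest tested TF by the tie rule
  nf <- as.integer(round(g2$session$duration * 60))
  flat <- tf_tuning(rep(2, nf), g2$session)
  expect_equal(flat$pref_tf, min(flat$tf_values))
  expect_true(flat$tie)
  expect_error(tf_tuning(rep(1, 100), small_session()$session), "TF-protocol")
})
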