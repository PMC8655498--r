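test_that("modulation and depth-of-modulation indices follow their definitions", {
  expect_equal(modulation_index(4, 4), 0)
  expect_equal(modulation_index(0, 4), -1)
  expect_equal(modulation_index(3, 1), 2)
  expect_equal(modulation_index(0, 0), 0)
  expect_error(modulation_index(-1, 2), "nonnegative")
  expect_equal(depth_of_modulation(4, 4), 0)
  expect_equal(depth_of_modulation(3, 0), 1)
  expect_equal(depth_of_modulation(3, 1), 0.5)
  expect_equal(depth_of_modulation(0, 0), 0)
  expect_error(depth_of_modulation(1, -2), "nonnegative")
  # bounds on random nonnegative rates
  set.seed(20)
  a <- rexp(500); b <- rexp(500)
  expect_true(all(abs(depth_of_modulation(a, b)) <= 1))
  expect_true(all(modulation_index(a, b) >= -1))
})

test_that("trial features match a brute-force windowed recomputation", {
  windows <- list(pre_perturbation = c(3.5, 4.5), perturbation = c(4.5, 5.5))
  flat <- rep(0.4, 600)
  f <- trial_features(flat, windows)
  expect_equal(unname(f[c("difference", "dm", "mi")]), c(0, 0, 0))
  expect_equal(unname(f["ratio"]), 1)
  set.seed(21)
  for (i in 1:20) {
    tr <- runif(600)
    f <- trial_features(tr, windows, eps = 0.1)
    r_pre <- oracle_window_mean(tr, windows$pre_perturbation)
    r_pert <- oracle_window_mean(tr, windows$perturbation)
    expect_equal(unname(f["ratio"]), r_pert / max(r_pre, 0.1))
    expect_equal(unname(f["difference"]), r_pert - r_pre)
    expect_equal(unname(f["combined_sum"]),
                 oracle_window_sum(tr, windows$pre_perturbation) +
                   oracle_window_sum(tr, windows$perturbation))
    expect_equal(unname(f["pert_sum"]), oracle_window_sum(tr, windows$perturbation))
    expect_equal(unname(f["dm"]), (r_pert - r_pre) / (r_pert + r_pre))
    expect_equal(unname(f["mi"]), (r_pert - r_pre) / max(r_pre, 0.1))
  }
})

test_that("ROC AUC equals the exhaustive pairwise statistic and is rank-invariant", {
  expect_equal(roc_auc(c(1, 2), c(0, 1)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both labels")
  set.seed(22)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(round(rnorm(n), 1))  # ties likely
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_identical(roc_auc(scores, labels), oracle_auc(scores, labels))
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(exp(3 * scores), labels), roc_auc(scores, labels))
  }
})

test_that("the logistic classifier scores behave at the information extremes", {
  set.seed(23)
  y <- rep(0:1, each = 10)
  # identical features: no information, all scores equal, AUC 0.5
  x_const <- matrix(1, 20, 6)
  fit <- fit_trial_classifier(x_const, y)
  expect_true(all(abs(fit$scores - fit$scores[1]) < 1e-12))
  expect_equal(roc_auc(fit$scores, y), 0.5)
  # one perfectly separating feature: AUC 1, separation flagged
  x_sep <- cbind(y * 2 - 1, matrix(rnorm(20 * 5), 20, 5))
  fit2 <- fit_trial_classifier(x_sep, y)
  expect_equal(roc_auc(fit2$scores, y), 1)
  expect_true(fit2$separation)
  expect_error(fit_trial_classifier(x_sep, rep(1, 20)), "each label")
})

test_that("the IRLS classifier reproduces stats::glm maximum-likelihood scores", {
  set.seed(25)
  for (i in 1:20) {
    n <- 80
    x <- matrix(rnorm(n * 6), n, 6)
    y <- rbinom(n, 1, 0.3)
    if (min(table(y)) < 2) next
    ours <- fit_trial_classifier(x, y)
    ref <- suppressWarnings(glm(y ~ scale(x), family = binomial()))
    expect_equal(ours$scores, unname(fitted(ref)), tolerance = 1e-4)
    expect_equal(roc_auc(ours$scores, y), roc_auc(fitted(ref), y))
  }
})

test_that("the shuffle null is reproducible and slightly optimistic in-sample", {
  # the six features of a real (null-cohort) unit over the standard
  # 160-trial protocol: correlated, as in actual sessions
  g <- generate_session(cohort_null(n_units = 1), seed = 24)
  rates <- session_rates(g$session)
  norm <- normalize_by_session_max(rates)
  tw <- pertflow:::session_trial_windows(g$session)
  x <- pertflow:::features_from_windows(norm$smoothed[1, ], tw,
                                        0.1 / norm$session_max[1])
  y <- as.integer(tw$trials$has_perturbation)
  set.seed(100); null1 <- shuffle_null(x, y, 50)
  set.seed(100); null2 <- shuffle_null(x, y, 50)
  expect_identical(null1, null2)
  expect_error(shuffle_null(x, y, 0), "n_shuffles")
  # in-sample fitting inflates the null mean a little above 0.5
  expect_gt(mean(null1), 0.48)
  expect_lt(mean(null1), 0.62)
})

test_that("strong perturbation responses of both signs are detected with the right sign", {
  seeds <- 1:4
  for (s in seeds) {
    g <- generate_session(recovery_config(1.5), seed = 300 + s)
    pr <- analyze_perturbation(g$session, n_shuffles = 200, seed = s)
    expect_true(pr$table$reliable)
    expect_equal(pr$table$sign, "positive")
    expect_gt(pr$table$mi_mean, 0.5)
  }
  for (s in seeds) {
    g <- generate_session(recovery_config(-0.8), seed = 400 + s)
    pr <- analyze_perturbation(g$session, n_shuffles = 200, seed = s)
    expect_true(pr$table$reliable)
    expect_equal(pr$table$sign, "negative")
    expect_lt(pr$table$mi_mean, -0.3)
  }
})

test_that("detection rate rises with modulation strength across a cohort", {
  mi_grid <- c(0, 0.25, 0.5, 1, 2)
  n_per <- 12L
  detected <- numeric(0); strength <- numeric(0)
  for (k in seq_along(mi_grid)) {
    g <- generate_session(recovery_config(mi_grid[k], n_units = n_per),
                          seed = 500 + k)
    pr <- analyze_perturbation(g$session, n_shuffles = 100, seed = k)
    detected <- c(detected, pr$table$reliable)
    strength <- c(strength, rep(mi_grid[k], n_per))
  }
  frac <- tapply(detected, strength, mean)
  expect_lt(frac[["0"]], 0.35)
  expect_gt(frac[["2"]], 0.9)
  # Cochran-Armitage trend across the |MI| grid (robust to saturation)
  tr <- prop.trend.test(tapply(detected, strength, sum),
                        tapply(detected, strength, length), score = mi_grid)
  expect_lt(tr$p.value, 0.01)
})

test_that("unit-level MI recovers the simulated ground truth", {
  # untuned units at baseline 10 sp/s, 40 perturbation trials each
  targets <- c(0.25, 0.5, 1)
  est <- lapply(targets, function(mi) {
    sapply(1:8, function(s) {
      g <- generate_session(recovery_config(mi), seed = 600 + 10 * mi * 4 + s)
      rates <- session_rates(g$session)
      norm <- normalize_by_session_max(rates)
      r <- classify_perturbation_unit(norm$smoothed[1, ], rates$raw[1, ],
                                      g$session, norm$session_max[1],
                                      n_shuffles = 5)
      r$mi_mean
    })
  })
  for (k in seq_along(targets)) {
    expect_lt(abs(mean(est[[k]]) - targets[k]), 0.1)
  }
  # pooled bias across targets
  bias <- mean(unlist(est) - rep(targets, each = 8))
  expect_lt(abs(bias), 0.05)
})
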