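# Independent pairwise-comparison oracle for the Mann-Whitney AUC.
auc_bruteforce <- function(scores, pos) {
  wins <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    wins <- wins + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  wins / (sum(pos) * sum(!pos))
}

test_that("AUC equals the pairwise win fraction with half-credit ties", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(10)
  for (i in 1:20) {
    s <- round(runif(30), 1)  # ties likely
    y <- rbinom(30, 1, 0.5) == 1
    if (any(y) && !all(y)) expect_equal(auc(s, y), auc_bruteforce(s, y))
  }
  expect_error(auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- runif(200); y <- rbinom(200, 1, 0.4)
  expect_equal(auc(s, y == 1),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("the volume-threshold sweep is exactly the ROC of volume as a score", {
  set.seed(21)
  for (i in 1:10) {
    v <- rlnorm(50, 9, 1)
    y <- rbinom(50, 1, 0.5)
    if (any(y == 1) && any(y == 0)) {
      expect_identical(volume_threshold_auc(v, y), auc(v, y))
    }
  }
  v <- c(1, 2, 10, 20)
  expect_equal(volume_threshold_auc(v, c(0, 0, 1, 1)), 1)
})

test_that("average precision follows the step-wise definition", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.2), c(0, 1)), 0.5)
  expect_equal(average_precision(c(0.3, 0.7), c(1, 1)), 1)
  # single positive at rank 3 of 4 distinct scores: AP = 1/3
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 1, 0)), 1 / 3)
  expect_error(average_precision(1:3, c(0, 0, 0)), "positives")
})

test_that("bootstrap AUC confidence intervals behave like percentiles", {
  set.seed(17)
  s <- c(rnorm(60, 0.6, 0.2), rnorm(60, 0.4, 0.2))
  y <- rep(c(TRUE, FALSE), each = 60)
  ci <- bootstrap_auc_ci(s, y, n_replicates = 500, seed = 5)
  point <- auc(s, y)
  expect_lte(ci[["low"]], point)
  expect_gte(ci[["high"]], point)
  expect_identical(ci, bootstrap_auc_ci(s, y, n_replicates = 500, seed = 5))
  # perfect separation collapses the interval at 1
  ci1 <- bootstrap_auc_ci(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                          n_replicates = 200, seed = 2)
  expect_equal(unname(ci1), c(1, 1))
  # intervals narrow as n grows
  make <- function(n, seed) {
    set.seed(seed)
    list(s = c(rnorm(n, 0.6, 0.25), rnorm(n, 0.4, 0.25)),
         y = rep(c(TRUE, FALSE), each = n))
  }
  small <- make(25, 1); big <- make(2500, 1)
  w_small <- diff(bootstrap_auc_ci(small$s, small$y, 400, seed = 9))
  w_big <- diff(bootstrap_auc_ci(big$s, big$y, 400, seed = 9))
  expect_gt(w_small, w_big)
})

test_that("the paired bootstrap AUC test detects differences and respects identity", {
  set.seed(33)
  y <- rep(c(TRUE, FALSE), each = 250)
  strong <- ifelse(y, rnorm(500, 0.8, 0.1), rnorm(500, 0.2, 0.1))
  noise <- runif(500)
  same <- bootstrap_auc_test(noise, noise, y, n_replicates = 200, seed = 1)
  expect_equal(same$p_value, 1)
  expect_equal(same$delta, 0)
  diffp <- bootstrap_auc_test(strong, noise, y, n_replicates = 500, seed = 1)
  expect_lt(diffp$p_value, 0.001)
  expect_gt(diffp$delta, 0.3)
  expect_error(bootstrap_auc_test(1:4, 1:5, c(TRUE, FALSE, TRUE, FALSE)), "length")
})

test_that("Fisher exact OR and p match the hypergeometric oracle", {
  flat <- fisher_exact_or(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$or, 1, tolerance = 1e-6)
  expect_equal(flat$p_value, 1)
  perfect <- fisher_exact_or(rbind(c(5, 0), c(0, 5)))
  expect_equal(perfect$or, Inf)
  expect_gt(perfect$ci_low, 1)
  tab <- rbind(c(20, 5), c(5, 20))
  got <- fisher_exact_or(tab)
  want <- cml_oracle(tab)
  # the reference implementation's root-finder carries ~1e-4 precision
  expect_equal(got$or, want$or, tolerance = 1e-3)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
  expect_true(got$significant)
  expect_error(fisher_exact_or(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(fisher_exact_or(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("feature ranking orders by adjusted OR and excludes zero coefficients", {
  co <- test_cohort(seed = 71, n = 80, hazard = 2.5)
  sch <- fit_volume_scheme(co, "rate_change")
  mp <- mining_params(0.3, 60, 2, 1)
  pats <- mine_patterns(encode_cohort(co, sch, "rate_change"), mp)
  feat <- build_feature_matrix(co, pats, mp, horizon(6), sch, "rate_change")
  idx <- downsample_majority(feat$label, seed = 2)
  fit <- fit_lasso_logistic(feat[idx, patternsurv:::feature_columns(feat)],
                            feat$label[idx], lambda = 0.01)
  ranks <- rank_patterns(fit, feat)
  if (nrow(ranks$le_horizon) > 1) {
    expect_true(all(diff(ranks$le_horizon$adj_or) <= 0))
  }
  expect_true(all(ranks$le_horizon$adj_or > 1))
  expect_true(all(ranks$gt_horizon$adj_or < 1))
  expect_false(any(c(ranks$le_horizon$feature, ranks$gt_horizon$feature) %in%
                     names(fit$coef)[fit$coef == 0]))
  # the planted sentinel ranks in the short-survival table with OR CI above 1
  keys <- attr(feat, "pattern_map")
  sentinel <- keys$column[keys$pattern == "neurologic_function=4"]
  row <- ranks$le_horizon[ranks$le_horizon$feature == sentinel, ]
  expect_equal(nrow(row), 1)
  expect_gt(row$ci_low, 1)
})

test_that("trajectory reports begin after the minimum documented history", {
  co <- test_cohort(seed = 81, n = 60, hazard = 2.5)
  grid <- data.frame(min_support = 0.3, max_gap_days = 60,
                     max_length = 3, max_size = 1)
  model <- select_model(grid, co, horizon(9), n_folds = 5, n_repeats = 1, seed = 5)
  # routine visits beginning on day 83 allow no prediction before day 203
  rec <- record_of("PX", days = c(83, 120, 160, 180, 203, 240),
                   outcome_day = 600)
  traj <- trajectory_report(rec, model)
  expect_true(all(traj$day >= 203))
  expect_true(all(traj$probability >= 0 & traj$probability <= 1))
  short <- record_of("PY", days = c(0, 30), outcome_day = 300)
  expect_equal(nrow(trajectory_report(short, model)), 0)
})
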