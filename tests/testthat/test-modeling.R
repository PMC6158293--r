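test_that("the two-step split is patient-disjoint, stratified and deterministic", {
  co <- lapply(1:100, function(i) {
    record_of(sprintf("P%03d", i), days = c(0, 30), outcome_day = 200 + i,
              sex = if (i %% 2 == 0) "male" else "female")
  })
  sp <- split_train_test(co, seed = 9)
  expect_length(sp$train, 75)
  expect_length(sp$test, 25)
  expect_length(intersect(sp$train, sp$test), 0)
  sex_of <- setNames(vapply(co, `[[`, "", "sex"), vapply(co, `[[`, "", "patient_id"))
  n_male_train <- sum(sex_of[sp$train] == "male")
  expect_true(n_male_train %in% 37:38)
  expect_identical(split_train_test(co, seed = 9), sp)
  expect_false(identical(split_train_test(co, seed = 10), sp))
  expect_error(split_train_test(co[1], seed = 1), "at least 4")
})

test_that("class proportions are preserved across the split on generator defaults", {
  co <- test_cohort(seed = 40, n = 304)
  sp <- split_train_test(co, seed = 2)
  ids <- vapply(co, `[[`, "", "patient_id")
  sch <- fit_volume_scheme(co[ids %in% sp$train], "rate_change")
  mp <- mining_params(0.3, 60, 2, 1)
  pat <- list(temporal_pattern(list("kps=unchanged")))
  frac_le <- function(recs) {
    f <- build_feature_matrix(recs, pat, mp, horizon(6), sch, "rate_change")
    mean(f$label == "le_horizon")
  }
  d <- abs(frac_le(co[ids %in% sp$train]) - frac_le(co[ids %in% sp$test]))
  expect_lt(d, 0.05)
})

test_that("down-sampling balances classes without touching the minority", {
  labels <- rep(c("gt", "le"), c(190, 10))
  idx <- downsample_majority(labels, seed = 3)
  expect_equal(as.vector(table(labels[idx])), c(10, 10))
  expect_true(all(which(labels == "le") %in% idx))
  balanced <- rep(c("gt", "le"), 5)
  expect_equal(downsample_majority(balanced, seed = 1), 1:10)
  expect_identical(downsample_majority(labels, seed = 3),
                   downsample_majority(labels, seed = 3))
  expect_error(downsample_majority(rep("gt", 5), seed = 1), "both classes")
})

test_that("LASSO logistic fits select separating features and report odds ratios", {
  set.seed(6)
  n <- 200
  x_signal <- rbinom(n, 1, 0.5)
  X <- cbind(sig = x_signal, noise1 = rbinom(n, 1, 0.5), noise2 = rbinom(n, 1, 0.5))
  y <- factor(ifelse(x_signal == 1, "le", "gt"), levels = c("gt", "le"))
  fit <- fit_lasso_logistic(X, y, lambda = 0.05)
  expect_true("sig" %in% fit$selected)
  expect_gt(fit$coef[["sig"]], 0)
  # direction agrees with the unpenalized fit on the same data (perfect
  # separation makes glm diverge in magnitude; only the sign is stable)
  glm_coef <- suppressWarnings(coef(glm(y ~ X, family = binomial()))[["Xsig"]])
  expect_equal(sign(fit$coef[["sig"]]), sign(glm_coef))
  expect_equal(unname(fit$adjusted_or[fit$coef == 0]),
               rep(1, sum(fit$coef == 0)))
  # an overwhelming penalty zeroes every coefficient
  fit0 <- fit_lasso_logistic(X, y, lambda = 10)
  expect_length(fit0$selected, 0)
  expect_error(fit_lasso_logistic(X, rep("le", n), lambda = 0.1), "two levels")
})

test_that("the number of selected features is non-increasing in lambda", {
  set.seed(77)
  n <- 150
  X <- matrix(rbinom(n * 12, 1, 0.4), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  eta <- X[, 1] * 1.5 - X[, 2] + rnorm(n, 0, 0.5)
  y <- factor(ifelse(runif(n) < plogis(eta), "le", "gt"), levels = c("gt", "le"))
  lambdas <- c(0.005, 0.02, 0.08, 0.3)
  nsel <- vapply(lambdas, function(l) {
    length(fit_lasso_logistic(X, y, l)$selected)
  }, 0L)
  expect_true(all(diff(nsel) <= 0))
})

test_that("cross-validation is patient-based, deterministic, and near 0.5 under permuted labels", {
  co <- test_cohort(seed = 52, n = 80, hazard = 2.5)
  sch <- fit_volume_scheme(co, "rate_change")
  mp <- mining_params(0.3, 60, 2, 1)
  pats <- mine_patterns(encode_cohort(co, sch, "rate_change"), mp)
  feat <- build_feature_matrix(co, pats, mp, horizon(6), sch, "rate_change")
  cv1 <- cross_validate(feat, n_folds = 5, n_repeats = 2, seed = 13)
  cv2 <- cross_validate(feat, n_folds = 5, n_repeats = 2, seed = 13)
  expect_identical(cv1, cv2)
  expect_gt(cv1$best_auc, 0.6)  # planted signal is recoverable
  # permuting labels patient-wise destroys the signal: with features
  # independent of the labels, the mean CV AUC sits near chance
  big <- test_cohort(seed = 41, n = 304)
  sch2 <- fit_volume_scheme(big, "rate_change")
  junk <- list(temporal_pattern(list("kps=unchanged")),
               temporal_pattern(list("mental_status=0")),
               temporal_pattern(list("kps=decreased", "mental_status=0")),
               temporal_pattern(list("neurologic_function=1")),
               temporal_pattern(list("overall_neuro_status=0")))
  perm <- build_feature_matrix(big, junk, mp, horizon(6), sch2, "rate_change")
  set.seed(99)
  pid <- unique(perm$patient_id)
  new_label <- setNames(sample(tapply(as.character(perm$label), perm$patient_id,
                                      function(x) x[1])[pid]), pid)
  perm$label <- factor(unname(new_label[perm$patient_id]),
                       levels = c("gt_horizon", "le_horizon"))
  perm <- perm[, c("patient_id", "day", "label",
                   paste0("pat_00", 1:5))]
  cvp <- suppressWarnings(cross_validate(perm, n_folds = 10, n_repeats = 3, seed = 3))
  expect_lt(abs(cvp$mean_auc[length(cvp$mean_auc)] - 0.5), 0.05)
})

test_that("threshold selection maximizes Youden's J", {
  scores <- c(rep(0.1, 5), rep(0.9, 5))
  labels <- rep(c(FALSE, TRUE), each = 5)
  expect_equal(choose_threshold(scores, labels), 0.5)
  set.seed(4)
  s2 <- c(rnorm(500, 0.4, 0.1), rnorm(500, 0.6, 0.1))
  l2 <- rep(c(FALSE, TRUE), each = 500)
  expect_lt(abs(choose_threshold(s2, l2) - 0.5), 0.05)
  expect_warning(t3 <- choose_threshold(rep(0.3, 10), rep(c(TRUE, FALSE), 5)),
                 "degenerate")
  expect_equal(t3, 0.5)
})

test_that("model selection returns the single-cell grid and is reproducible", {
  co <- test_cohort(seed = 61, n = 70, hazard = 2.5)
  grid <- data.frame(min_support = 0.3, max_gap_days = 60,
                     max_length = 2, max_size = 1)
  m1 <- select_model(grid, co, horizon(6), n_folds = 5, n_repeats = 1, seed = 8)
  expect_equal(m1$config$min_support, 0.3)
  expect_s3_class(m1$fit, "fit_result")
  expect_true(is.finite(m1$cv_auc))
  m2 <- select_model(grid, co, horizon(6), n_folds = 5, n_repeats = 1, seed = 8)
  expect_equal(m1[c("fit", "threshold", "cv_auc", "lambda")],
               m2[c("fit", "threshold", "cv_auc", "lambda")])
  expect_error(select_model(grid[0, ], co, horizon(6)), "empty")
})
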