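# Interpret labels as a logical positive-class indicator.
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  x <- as.character(labels)
  if (any(x == "le_horizon")) return(x == "le_horizon")
  lv <- sort(unique(x))
  if (length(lv) > 2) stop_input("labels must be binary")
  x == lv[length(lv)]
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or `le_horizon`/`gt_horizon`).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_input("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of the tumor-volume threshold classifier
#'
#' Predicting short residual survival whenever the tumor volume exceeds a
#' threshold, evaluated across all possible thresholds, traces exactly the
#' ROC curve of the volume used as a score — so this equals
#' `auc(volumes, labels)` on all inputs.
#'
#' @param volumes Tumor volumes used as the ranking score.
#' @inheritParams auc
#' @export
volume_threshold_auc <- function(volumes, labels) auc(volumes, labels)

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise definition: precision at each distinct score level, weighted
#' by the recall increment it contributes.
#'
#' @inheritParams auc
#' @export
average_precision <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos)
  if (n1 == 0) stop_input("average precision undefined without positives")
  o <- order(scores, decreasing = TRUE)
  y <- pos[o]; s <- scores[o]
  n <- length(s)
  last <- which(s != c(s[-1], NA_real_) | seq_len(n) == n)
  tp <- cumsum(y)[last]
  precision <- tp / last
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

# Stratified bootstrap resample indices (within-class resampling).
strat_resample <- function(pos) {
  ip <- which(pos); ineg <- which(!pos)
  c(ip[sample.int(length(ip), replace = TRUE)],
    ineg[sample.int(length(ineg), replace = TRUE)])
}

#' Percentile bootstrap confidence interval for an AUC
#'
#' Resamples within each class (stratified) and returns the percentile
#' 95\% interval over the replicates.
#'
#' @inheritParams auc
#' @param n_replicates Number of bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_replicates = 2000, seed = 1L,
                             conf = 0.95) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) stop_input("both classes must be present")
  bs <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      idx <- strat_resample(pos)
      auc(scores[idx], pos[idx])
    }, 0)
  })
  a <- (1 - conf) / 2
  stats::setNames(as.numeric(stats::quantile(bs, c(a, 1 - a), names = FALSE)),
                  c("low", "high"))
}

#' Paired bootstrap test for a difference in AUC
#'
#' Both score vectors must be computed on the identical visits. The test
#' resamples visits (stratified by class), recomputes the AUC difference on
#' each replicate, and forms the normal-deviate statistic
#' `z = observed difference / bootstrap SD of the difference`, with a
#' two-sided p-value.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @inheritParams bootstrap_auc_ci
#' @return List with `p_value`, `delta` (AUC_a - AUC_b), `z`,
#'   `n_replicates` and `variant` (the statistic used).
#' @export
bootstrap_auc_test <- function(scores_a, scores_b, labels, n_replicates = 2000,
                               seed = 1L) {
  if (length(scores_a) != length(scores_b)) {
    stop_input("paired scores must have identical length")
  }
  pos <- as_positive(labels)
  if (length(pos) != length(scores_a)) stop_input("labels length mismatch")
  delta <- auc(scores_a, pos) - auc(scores_b, pos)
  d_star <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      idx <- strat_resample(pos)
      auc(scores_a[idx], pos[idx]) - auc(scores_b[idx], pos[idx])
    }, 0)
  })
  s <- stats::sd(d_star)
  if (!is.finite(s) || s == 0) {
    p <- if (abs(delta) < 1e-12) 1 else 0
    z <- if (abs(delta) < 1e-12) 0 else Inf
  } else {
    z <- delta / s
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p_value = p, delta = delta, z = z, n_replicates = n_replicates,
       variant = "paired stratified bootstrap, normal-deviate difference")
}

#' Fisher's exact test and conditional-ML odds ratio for a 2x2 table
#'
#' Conditional maximum-likelihood odds ratio with exact 95\% CI and
#' two-sided p-value (no continuity/Haldane correction; zero cells give
#' 0 or Inf estimates with finite one-sided CI bounds). Significance is
#' judged at alpha = 0.05.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows: exposure; columns: outcome).
#' @return List with `or`, `ci_low`, `ci_high`, `p_value`, `significant`.
#' @export
fisher_exact_or <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop_input("table must be a 2x2 matrix of non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_input("odds ratio undefined: a margin of the table is zero")
  }
  ft <- stats::fisher.test(table)
  list(or = unname(ft$estimate), ci_low = ft$conf.int[1],
       ci_high = ft$conf.int[2], p_value = ft$p.value,
       significant = ft$p.value < 0.05)
}

#' Rank a model's selected features by adjusted odds ratio
#'
#' Two tables: features predicting short residual survival (adjusted
#' OR > 1, descending) and long residual survival (adjusted OR < 1,
#' ascending), each with patient-level support (patterns only) and the
#' univariate exact-test odds ratio of visit-level occurrence vs. label.
#'
#' @param model A `resid_model` (or bare `fit_result` plus `pattern_map`).
#' @param feat Labeled feature matrix the univariate statistics are
#'   computed on.
#' @param top_n Rows per table (default 10).
#' @return List with data frames `le_horizon` and `gt_horizon`.
#' @export
rank_patterns <- function(model, feat, top_n = 10) {
  fit <- if (inherits(model, "resid_model")) model$fit else model
  pmap <- attr(feat, "pattern_map")
  sel <- fit$selected
  if (length(sel) == 0) {
    empty <- data.frame(feature = character(0), pattern = character(0),
                        support = numeric(0), adj_or = numeric(0),
                        uni_or = numeric(0), ci_low = numeric(0),
                        ci_high = numeric(0), p_value = numeric(0))
    return(list(le_horizon = empty, gt_horizon = empty))
  }
  pos <- feat$label == "le_horizon"
  rows <- lapply(sel, function(f) {
    occ <- feat[[f]] > 0
    tab <- rbind(c(sum(occ & pos), sum(occ & !pos)),
                 c(sum(!occ & pos), sum(!occ & !pos)))
    uni <- tryCatch(fisher_exact_or(tab),
                    error = function(e) list(or = NA, ci_low = NA,
                                             ci_high = NA, p_value = NA))
    i <- match(f, pmap$column)
    data.frame(feature = f,
               pattern = if (!is.na(i)) pmap$pattern[i] else f,
               support = if (!is.na(i)) pmap$support[i] else NA_real_,
               adj_or = unname(fit$adjusted_or[f]),
               uni_or = uni$or, ci_low = uni$ci_low, ci_high = uni$ci_high,
               p_value = uni$p_value)
  })
  stats <- do.call(rbind, rows)
  le <- stats[stats$adj_or > 1, , drop = FALSE]
  gt <- stats[stats$adj_or < 1, , drop = FALSE]
  le <- le[order(-le$adj_or), , drop = FALSE]
  gt <- gt[order(gt$adj_or), , drop = FALSE]
  list(le_horizon = utils::head(le, top_n), gt_horizon = utils::head(gt, top_n))
}

#' Per-visit probability trajectory of one patient
#'
#' Scores every predictable visit of the record (those with at least the
#' model's minimum documented history); the first predictable day is the
#' first visit day plus [min_history_required()]. Visits of alive patients
#' whose label is indeterminable are reported with `label = NA`.
#'
#' @param record One patient record.
#' @param model A `resid_model`.
#' @return Data frame with `day`, `probability`, `predicted`, `label`.
#' @export
trajectory_report <- function(record, model) {
  feat <- build_feature_matrix(list(record), model$patterns, model$mining,
                               model$horizon, model$scheme,
                               model$representation, "optimistic")
  if (nrow(feat) == 0) {
    return(data.frame(day = integer(0), probability = numeric(0),
                      predicted = character(0), label = character(0)))
  }
  true_label <- label_visit(feat$day, record$outcome_day, record$deceased,
                            model$horizon, "exclude")
  p <- predict(model$fit, feat)
  data.frame(day = feat$day, probability = p,
             predicted = ifelse(p >= model$threshold, "le_horizon", "gt_horizon"),
             label = true_label)
}

# Visit-level table (volume + covariates + label) for the two baseline
# approaches; rows are visits with a volume measurement and a determinable
# label.
volume_visit_table <- function(records, horizon, censor_policy = "exclude") {
  out <- lapply(records, function(r) {
    vs <- r$visits
    m <- which(!is.na(vs$volume_mm3))
    if (length(m) == 0) return(NULL)
    lab <- label_visit(vs$day[m], r$outcome_day, r$deceased, horizon, censor_policy)
    keep <- !is.na(lab)
    if (!any(keep)) return(NULL)
    cbind(data.frame(patient_id = r$patient_id, day = vs$day[m][keep],
                     volume_mm3 = vs$volume_mm3[m][keep],
                     label = lab[keep]),
          as.data.frame(covariate_matrix(r, vs$day[m][keep])))
  })
  res <- do.call(rbind, Filter(Negate(is.null), out))
  res$label <- factor(res$label, levels = c("gt_horizon", "le_horizon"))
  res
}

#' Compare the three residual-survival prediction approaches
#'
#' Approach 1 thresholds the raw tumor volume; approach 2 is a logistic
#' model on volume plus patient covariates (fit on the down-sampled
#' training visits); approach 3 is the temporal-pattern model. Each is
#' evaluated on its usable test visits with a stratified bootstrap CI; the
#' paired bootstrap tests compare approaches on the visits common to both.
#'
#' @param model A fitted `resid_model`.
#' @param train_records,test_records Training and test partitions.
#' @param n_replicates Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return List with a per-approach `summary` data frame (AUC, CI, average
#'   precision, n visits) and `tests`, the paired bootstrap comparisons of
#'   the pattern model against each baseline.
#' @export
compare_approaches <- function(model, train_records, test_records,
                               n_replicates = 2000, seed = 1L) {
  hz <- model$horizon
  vol_train <- volume_visit_table(train_records, hz)
  vol_test <- volume_visit_table(test_records, hz)
  # approach 1: volume threshold sweep
  auc1 <- volume_threshold_auc(vol_test$volume_mm3, vol_test$label)
  ci1 <- bootstrap_auc_ci(vol_test$volume_mm3, vol_test$label, n_replicates,
                          substream_seed(seed, "ci1"))
  ap1 <- average_precision(vol_test$volume_mm3, vol_test$label)
  # approach 2: volume + covariates logistic model
  ds <- downsample_majority(vol_train$label, substream_seed(seed, "ds2"))
  covs <- grep("^cov_", names(vol_train), value = TRUE)
  covs <- covs[vapply(vol_train[ds, covs], function(x) length(unique(x)) > 1, TRUE)]
  f <- stats::as.formula(paste("label ~ volume_mm3 +", paste(covs, collapse = "+")))
  glm2 <- suppressWarnings(stats::glm(f, data = vol_train[ds, ],
                                      family = stats::binomial()))
  p2 <- suppressWarnings(stats::predict(glm2, newdata = vol_test, type = "response"))
  auc2 <- auc(p2, vol_test$label)
  ci2 <- bootstrap_auc_ci(p2, vol_test$label, n_replicates,
                          substream_seed(seed, "ci2"))
  ap2 <- average_precision(p2, vol_test$label)
  # approach 3: temporal patterns + covariates
  sc3 <- score_records(model, test_records)
  auc3 <- auc(sc3$probability, sc3$label)
  ci3 <- bootstrap_auc_ci(sc3$probability, sc3$label, n_replicates,
                          substream_seed(seed, "ci3"))
  ap3 <- average_precision(sc3$probability, sc3$label)
  summary <- data.frame(
    approach = c("volume_only", "volume_plus_covariates", "patterns_plus_covariates"),
    auc = c(auc1, auc2, auc3),
    ci_low = c(ci1["low"], ci2["low"], ci3["low"]),
    ci_high = c(ci1["high"], ci2["high"], ci3["high"]),
    average_precision = c(ap1, ap2, ap3),
    n_visits = c(nrow(vol_test), nrow(vol_test), nrow(sc3)))
  # paired tests on common visits
  key3 <- paste(sc3$patient_id, sc3$day)
  keyv <- paste(vol_test$patient_id, vol_test$day)
  common <- intersect(key3, keyv)
  i3 <- match(common, key3); iv <- match(common, keyv)
  tests <- list(
    patterns_vs_volume = bootstrap_auc_test(
      sc3$probability[i3], vol_test$volume_mm3[iv], sc3$label[i3],
      n_replicates, substream_seed(seed, "t31")),
    patterns_vs_volume_covariates = bootstrap_auc_test(
      sc3$probability[i3], p2[iv], sc3$label[i3],
      n_replicates, substream_seed(seed, "t32")))
  list(summary = summary, tests = tests, n_common_visits = length(common))
}
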