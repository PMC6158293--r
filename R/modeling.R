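#' Two-step stratified patient-level train/test split
#'
#' Patients are first separated by whether their overall survival (outcome
#' day) is below the cohort mean, then each survival subgroup is split
#' 75/25 while conserving the proportion of males to females, and the
#' partitions are merged. Every patient is wholly in train or test. Strata
#' with fewer than 4 patients are merged upward (survival subgroup only,
#' then the whole cohort) with a warning.
#'
#' @param records Patient records.
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with character vectors `train` and `test` of patient ids.
#' @export
split_train_test <- function(records, train_frac = 0.75, seed = 1L) {
  if (length(records) < 4) stop_input("need at least 4 patients for a split")
  ids <- vapply(records, `[[`, "", "patient_id")
  os <- vapply(records, `[[`, 0, "outcome_day")
  sex <- vapply(records, `[[`, "", "sex")
  subgroup <- ifelse(os < mean(os), "lowOS", "highOS")
  stratum <- paste(subgroup, sex, sep = ".")
  counts <- table(stratum)
  small <- names(counts)[counts < 4]
  if (length(small)) {
    warning("merging small strata upward: ", paste(small, collapse = ", "))
    stratum[stratum %in% small] <- subgroup[stratum %in% small]
    counts <- table(stratum)
    small <- names(counts)[counts < 4]
    if (length(small)) stratum[stratum %in% small] <- "all"
  }
  groups <- split(ids, stratum)
  # largest-remainder allocation: per-stratum train counts within one of
  # the exact target, overall train count exactly round(train_frac * n)
  target <- train_frac * lengths(groups)
  n_train <- floor(target)
  remainder <- round(train_frac * length(ids)) - sum(n_train)
  if (remainder > 0) {
    give <- order(-(target - n_train), names(groups))[seq_len(remainder)]
    n_train[give] <- n_train[give] + 1L
  }
  with_seed(seed, {
    train <- unlist(lapply(seq_along(groups), function(i) {
      g <- sample(groups[[i]])
      g[seq_len(n_train[i])]
    }), use.names = FALSE)
    list(train = sort(train), test = sort(setdiff(ids, train)))
  })
}

#' Down-sample the majority class to a balanced subset
#'
#' Randomly drops majority-class rows until both classes have the minority
#' count; the minority class is untouched. Applied only inside training
#' folds and the final training fit, never to validation or test data.
#'
#' @param labels Two-level factor or character vector of class labels.
#' @param seed Integer seed.
#' @return Sorted integer indices of the retained rows.
#' @export
downsample_majority <- function(labels, seed = 1L) {
  tab <- table(as.character(labels))
  if (length(tab) < 2) stop_input("both classes must be present to down-sample")
  minority_n <- min(tab)
  with_seed(seed, {
    keep <- unlist(lapply(names(tab), function(cl) {
      idx <- which(as.character(labels) == cl)
      if (length(idx) > minority_n) sample(idx, minority_n) else idx
    }), use.names = FALSE)
    sort(keep)
  })
}

#' Fit an L1-penalized (LASSO) logistic regression
#'
#' Binary 0/1 pattern features and covariate indicators are on a common
#' scale, so no standardization is applied. The adjusted odds ratio of a
#' feature is `exp(coefficient)`; unselected (zero-coefficient) features
#' have adjusted OR 1.
#'
#' @param X Numeric feature matrix.
#' @param y Two-level factor/character/0-1 label vector; the second level
#'   (or 1) is the event class.
#' @param lambda Regularization strength.
#' @return List of class `fit_result`: `coef` (named, zeros included),
#'   `intercept`, `lambda`, `selected`, `adjusted_or`.
#' @export
fit_lasso_logistic <- function(X, y, lambda) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop_input("labels must have exactly two levels")
  if (length(unique(y)) < 2) stop_input("labels are constant")
  path <- sort(unique(lambda * c(32, 16, 8, 4, 2, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(as.matrix(X), y, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE)
  cf <- as.matrix(stats::coef(fit, s = lambda))[, 1]
  coefs <- cf[-1]
  structure(list(coef = coefs, intercept = unname(cf[1]), lambda = lambda,
                 selected = names(coefs)[coefs != 0],
                 adjusted_or = exp(coefs)),
            class = "fit_result")
}

#' @export
predict.fit_result <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, names(object$coef), drop = FALSE])
  } else newdata[, names(object$coef), drop = FALSE]
  as.numeric(stats::plogis(object$intercept + X %*% object$coef))
}

# Logarithmic lambda path from the data's lambda_max down to 5% of it.
# The floor keeps the fits sparse (the pattern features are heavily nested
# and therefore strongly correlated; very small lambdas select hundreds of
# near-duplicate patterns and add nothing but runtime).
default_lambda_path <- function(feat, seed, n_lambda = 8, min_ratio = 0.05) {
  X <- as.matrix(feat[, feature_columns(feat), drop = FALSE])
  idx <- downsample_majority(feat$label, substream_seed(seed, "lambda_path"))
  y <- as.numeric(feat$label[idx] == levels(feat$label)[2])
  # entry point of the first feature for the unstandardized binomial lasso
  lam_max <- max(abs(crossprod(X[idx, , drop = FALSE], y - mean(y)))) / length(y)
  lam_max * exp(seq(0, log(min_ratio), length.out = n_lambda))
}

#' Repeated patient-level cross-validation of the LASSO path
#'
#' Folds are patient-based: patients in the validation fold contribute no
#' visits to the training folds (asserted on every fold). Down-sampling is
#' applied inside each training fold only. The procedure runs
#' `n_repeats` times with different fold seeds and averages AUC and
#' average precision per lambda. Folds whose validation part has one class
#' are skipped with a warning.
#'
#' @param feat Labeled feature matrix from [build_feature_matrix()].
#' @param lambdas Decreasing lambda path; default derives one from the data.
#' @param n_folds,n_repeats Fold count (default 10) and repeats (default 3).
#' @param seed Integer seed.
#' @return List with `lambda`, `mean_auc`, `mean_ap`, `best_lambda`,
#'   `best_auc`, `best_ap`.
#' @export
cross_validate <- function(feat, lambdas = NULL, n_folds = 10, n_repeats = 3,
                           seed = 1L) {
  patients <- unique(feat$patient_id)
  if (length(patients) < n_folds) stop_input("need at least n_folds patients")
  if (is.null(lambdas)) lambdas <- default_lambda_path(feat, seed)
  lambdas <- sort(unique(lambdas), decreasing = TRUE)
  X <- as.matrix(feat[, feature_columns(feat), drop = FALSE])
  auc_acc <- matrix(NA_real_, nrow = n_repeats * n_folds, ncol = length(lambdas))
  ap_acc <- auc_acc
  row <- 0L
  for (r in seq_len(n_repeats)) {
    fold_of <- with_seed(substream_seed(seed, paste0("cvfold", r)), {
      stats::setNames(rep(seq_len(n_folds), length.out = length(patients)),
                      sample(patients))
    })
    for (f in seq_len(n_folds)) {
      row <- row + 1L
      val_patients <- names(fold_of)[fold_of == f]
      val <- feat$patient_id %in% val_patients
      stopifnot(length(intersect(feat$patient_id[!val], val_patients)) == 0)
      y_val <- feat$label[val]
      if (length(unique(y_val)) < 2 || !any(val) ||
          length(unique(feat$label[!val])) < 2) {
        warning(sprintf("fold %d of repeat %d skipped (single class)", f, r))
        next
      }
      tr_idx <- which(!val)
      ds <- downsample_majority(feat$label[tr_idx],
                                substream_seed(seed, sprintf("ds%d.%d", r, f)))
      tr_idx <- tr_idx[ds]
      fit <- glmnet::glmnet(X[tr_idx, , drop = FALSE], feat$label[tr_idx],
                            family = "binomial", alpha = 1,
                            lambda = lambdas, standardize = FALSE)
      pr <- stats::predict(fit, X[val, , drop = FALSE], s = lambdas,
                           type = "response")
      pos <- y_val == levels(feat$label)[2]
      for (k in seq_len(ncol(pr))) {
        auc_acc[row, k] <- auc(pr[, k], pos)
        ap_acc[row, k] <- average_precision(pr[, k], pos)
      }
    }
  }
  mean_auc <- colMeans(auc_acc, na.rm = TRUE)
  mean_ap <- colMeans(ap_acc, na.rm = TRUE)
  best <- which.max(mean_auc)
  list(lambda = lambdas, mean_auc = mean_auc, mean_ap = mean_ap,
       best_lambda = lambdas[best], best_auc = mean_auc[best],
       best_ap = mean_ap[best])
}

#' Classification threshold maximizing Youden's J on training predictions
#'
#' Candidate thresholds are midpoints between consecutive distinct scores;
#' the one maximizing sensitivity + specificity - 1 is returned (the
#' median midpoint under ties). Degenerate score vectors fall back to 0.5
#' with a warning.
#'
#' @param scores Predicted probabilities on the training partition.
#' @param labels Logical or two-level labels (positive = event class).
#' @return A probability threshold.
#' @export
choose_threshold <- function(scores, labels) {
  pos <- as_positive(labels)
  u <- sort(unique(scores))
  if (length(u) < 2 || length(unique(pos)) < 2) {
    warning("degenerate scores or labels; returning threshold 0.5")
    return(0.5)
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(t) {
    mean(scores[pos] >= t) - mean(scores[!pos] >= t)
  }, 0)
  best <- cand[j >= max(j) - 1e-12]
  stats::median(best)
}

#' Mining-parameter grid search with repeated CV, and final refit
#'
#' For each mining configuration: fits the discretization on the training
#' records, encodes, mines, builds the labeled feature matrix, and scores
#' a lambda path by repeated patient-level CV AUC. The configuration (and
#' lambda) with the highest mean CV AUC wins; ties are broken by fewer
#' selected features after refit, then by lexicographic parameter order.
#' The winner is refit on the whole (down-sampled) training partition.
#'
#' @param grid Data frame with columns `min_support`, `max_gap_days`,
#'   `max_length`, `max_size`.
#' @param train_records Training patient records.
#' @param horizon A [horizon()] object.
#' @param representation Volume representation (default `"rate_change"`).
#' @param k_bins Equal-frequency states for continuous representations.
#' @param n_folds,n_repeats,lambdas Passed to [cross_validate()].
#' @param censor_policy Passed to [build_feature_matrix()].
#' @param seed Integer seed.
#' @return List of class `resid_model`: winning `config`, `mining`
#'   parameters, `scheme`, `patterns`, `fit` (`fit_result`), `threshold`,
#'   `cv_auc`, `cv_ap`, `horizon`, `representation`.
#' @export
select_model <- function(grid, train_records, horizon,
                         representation = "rate_change", k_bins = 10,
                         n_folds = 10, n_repeats = 3, lambdas = NULL,
                         censor_policy = "exclude", seed = 1L) {
  if (nrow(grid) == 0) stop_input("empty parameter grid")
  scheme <- fit_volume_scheme(train_records, representation, k = k_bins)
  sequences <- NULL
  cand <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    mp <- mining_params(grid$min_support[g], grid$max_gap_days[g],
                        grid$max_length[g], grid$max_size[g])
    if (is.null(sequences)) {
      sequences <- encode_cohort(train_records, scheme, representation)
    }
    patterns <- mine_patterns(sequences, mp)
    if (length(patterns) == 0) {
      warning(sprintf("grid row %d mined no patterns; skipped", g))
      next
    }
    feat <- build_feature_matrix(train_records, patterns, mp, horizon,
                                 scheme, representation, censor_policy)
    if (nrow(feat) == 0 || length(unique(feat$label)) < 2) {
      warning(sprintf("grid row %d yields a degenerate feature matrix; skipped", g))
      next
    }
    cv <- cross_validate(feat, lambdas = lambdas, n_folds = n_folds,
                         n_repeats = n_repeats,
                         seed = substream_seed(seed, sprintf("grid%d", g)))
    cand[[g]] <- list(g = g, mining = mp, patterns = patterns, feat = feat, cv = cv)
  }
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0) stop_input("all grid configurations were degenerate")
  aucs <- vapply(cand, function(c) c$cv$best_auc, 0)
  top <- which(aucs >= max(aucs) - 1e-12)
  refit_one <- function(c) {
    idx <- downsample_majority(c$feat$label,
                               substream_seed(seed, sprintf("refit%d", c$g)))
    X <- c$feat[idx, feature_columns(c$feat), drop = FALSE]
    fit_lasso_logistic(X, c$feat$label[idx], c$cv$best_lambda)
  }
  fits <- lapply(cand[top], refit_one)
  nsel <- vapply(fits, function(f) length(f$selected), 0L)
  ord <- order(nsel, vapply(cand[top], function(c) c$g, 0L))[1]
  winner <- cand[top][[ord]]
  fit <- fits[[ord]]
  scores <- predict(fit, winner$feat)
  thr <- choose_threshold(scores, winner$feat$label == "le_horizon")
  structure(list(config = grid[winner$g, , drop = FALSE],
                 mining = winner$mining, scheme = scheme,
                 patterns = winner$patterns, fit = fit,
                 threshold = thr, cv_auc = winner$cv$best_auc,
                 cv_ap = winner$cv$best_ap, lambda = winner$cv$best_lambda,
                 horizon = horizon, representation = representation,
                 censor_policy = censor_policy, seed = seed),
            class = "resid_model")
}

#' Per-visit predicted probabilities of a fitted residual-survival model
#'
#' Rebuilds the feature matrix for `records` using the model's own
#' (training-fitted) discretization scheme and patterns, then scores each
#' predictable visit.
#'
#' @param model A `resid_model` from [select_model()].
#' @param records Patient records to score.
#' @param censor_policy Labeling policy for the returned `label` column.
#' @return The feature matrix restricted to `patient_id`, `day`, `label`,
#'   plus `probability` and `predicted` (probability >= threshold).
#' @export
score_records <- function(model, records, censor_policy = model$censor_policy) {
  feat <- build_feature_matrix(records, model$patterns, model$mining,
                               model$horizon, model$scheme,
                               model$representation, censor_policy)
  p <- predict(model$fit, feat)
  data.frame(patient_id = feat$patient_id, day = feat$day, label = feat$label,
             probability = p,
             predicted = ifelse(p >= model$threshold, "le_horizon", "gt_horizon"))
}

#' Serialize a fitted model to JSON
#'
#' Records feature names, nonzero coefficients, lambda, threshold, mining
#' parameters and seed so a run is reproducible from its artifacts.
#' @param model A `resid_model`.
#' @param path Output path.
#' @export
model_to_json <- function(model, path) {
  sel <- model$fit$selected
  jsonlite::write_json(list(
    horizon_months = model$horizon$months,
    representation = model$representation,
    mining = unclass(model$mining),
    lambda = model$lambda,
    threshold = model$threshold,
    intercept = model$fit$intercept,
    cv_auc = model$cv_auc, cv_ap = model$cv_ap,
    seed = model$seed,
    coefficients = as.list(model$fit$coef[sel]),
    adjusted_or = as.list(model$fit$adjusted_or[sel]),
    pattern_map = attr(model$patterns, "pattern_map") %||% NULL
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
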