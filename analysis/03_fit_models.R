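#!/usr/bin/env Rscript

# Stage 3: fit the residual-survival models.
#
# For each horizon (2, 6, 9 months), runs the mining-parameter grid search
# with 3x10-fold patient-level cross-validation and majority down-sampling
# on the training partition, refits the winner with the LASSO at its
# CV-selected lambda, and serializes the model. The grid here holds two
# cells (support 0.30/0.35, gap 60, length 2, size 2) so the whole stage
# runs in a few minutes; widen it for a fuller search.

suppressMessages(library(patternsurv))

cohort <- read_cohort("results/cohort")
split <- jsonlite::read_json("results/split.json", simplifyVector = TRUE)
ids <- vapply(cohort, `[[`, "", "patient_id")
train <- cohort[ids %in% split$train]

grid <- data.frame(min_support = c(0.30, 0.35), max_gap_days = 60,
                   max_length = 2, max_size = 2)

for (hm in c(2, 6, 9)) {
  model <- select_model(grid, train, horizon(hm), n_folds = 10, n_repeats = 3,
                        seed = 300 + hm)
  model_to_json(model, sprintf("results/model_h%d.json", hm))
  saveRDS(model, sprintf("results/model_h%d.rds", hm))  # scratch for stage 4
  cat(sprintf(
    "%d-month model: support %.2f, lambda %.4g, CV AUC %.3f, CV AP %.3f, %d features\n",
    hm, model$config$min_support, model$lambda, model$cv_auc, model$cv_ap,
    length(model$fit$selected)))
}
cat("Models written to results/model_h{2,6,9}.json\n")
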