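#' Configuration of an end-to-end residual-survival run
#'
#' @param cohort Either a [cohort_params()] object (a synthetic cohort is
#'   generated) or a directory containing `patients.csv`/`visits.csv`.
#' @param grid Mining-parameter grid (data frame with `min_support`,
#'   `max_gap_days`, `max_length`, `max_size`).
#' @param horizons Subset of `c(2, 6, 9)` months.
#' @param representation Volume representation for encoding.
#' @param train_frac,n_folds,n_repeats,censor_policy Modeling settings.
#' @param n_replicates Bootstrap replicates for the evaluation stage.
#' @param out_dir Output directory for run artifacts.
#' @param seed Top-level seed; every random draw flows from it through
#'   named substreams.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_params(),
                       grid = data.frame(min_support = 0.3, max_gap_days = 60,
                                         max_length = 3, max_size = 3),
                       horizons = c(2, 6, 9),
                       representation = "rate_change",
                       train_frac = 0.75, n_folds = 10, n_repeats = 3,
                       censor_policy = "exclude",
                       n_replicates = 2000,
                       out_dir = "results/run", seed = 1L) {
  assert_that(nrow(grid) >= 1, "grid must be non-empty")
  assert_that(all(horizons %in% c(2, 6, 9)), "horizons must be within {2, 6, 9}")
  structure(list(cohort = cohort, grid = grid, horizons = horizons,
                 representation = representation, train_frac = train_frac,
                 n_folds = n_folds, n_repeats = n_repeats,
                 censor_policy = censor_policy, n_replicates = n_replicates,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis: simulate/load, encode, mine, fit, evaluate
#'
#' Executes the workflow per horizon and writes its artifacts under
#' `config$out_dir`: the cohort CSVs, mined patterns (JSON lines), the
#' labeled feature matrix with its pattern sidecar, the model JSON, metric
#' and pattern-ranking CSVs, a per-patient trajectory report, and a
#' manifest recording the configuration and seeds.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the fitted models, approach comparisons
#'   and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (inherits(config$cohort, "cohort_params")) {
    generate_cohort(config$cohort)
  } else {
    read_cohort(config$cohort)
  }
  write_cohort(records, file.path(config$out_dir, "cohort"))
  utils::write.csv(cohort_summary(records),
                   file.path(config$out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  split <- split_train_test(records, config$train_frac,
                            substream_seed(config$seed, "split"))
  ids <- vapply(records, `[[`, "", "patient_id")
  train <- records[ids %in% split$train]
  test <- records[ids %in% split$test]
  models <- list()
  comparisons <- list()
  for (hm in config$horizons) {
    hz <- horizon(hm)
    tag <- sprintf("h%d", hm)
    model <- select_model(config$grid, train, hz,
                          representation = config$representation,
                          n_folds = config$n_folds,
                          n_repeats = config$n_repeats,
                          censor_policy = config$censor_policy,
                          seed = substream_seed(config$seed, tag))
    writeLines(vapply(model$patterns, function(p) {
      jsonlite::toJSON(list(elements = p$elements, support = p$support),
                       auto_unbox = TRUE, digits = NA)
    }, ""), file.path(config$out_dir, sprintf("patterns_%s.jsonl", tag)))
    feat <- build_feature_matrix(train, model$patterns, model$mining, hz,
                                 model$scheme, model$representation,
                                 config$censor_policy)
    write_feature_matrix(feat, file.path(config$out_dir, sprintf("features_%s", tag)))
    model_to_json(model, file.path(config$out_dir, sprintf("model_%s.json", tag)))
    cmp <- compare_approaches(model, train, test,
                              n_replicates = config$n_replicates,
                              seed = substream_seed(config$seed, paste0("cmp", tag)))
    utils::write.csv(cmp$summary,
                     file.path(config$out_dir, sprintf("metrics_%s.csv", tag)),
                     row.names = FALSE)
    ranks <- rank_patterns(model, feat)
    utils::write.csv(ranks$le_horizon,
                     file.path(config$out_dir, sprintf("top_patterns_le_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(ranks$gt_horizon,
                     file.path(config$out_dir, sprintf("top_patterns_gt_%s.csv", tag)),
                     row.names = FALSE)
    traj <- trajectory_report(test[[1]], model)
    utils::write.csv(traj,
                     file.path(config$out_dir, sprintf("trajectory_%s.csv", tag)),
                     row.names = FALSE)
    models[[tag]] <- model
    comparisons[[tag]] <- cmp
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("patternsurv")),
    seed = config$seed,
    grid = config$grid,
    horizons = config$horizons,
    representation = config$representation,
    censor_policy = config$censor_policy,
    n_folds = config$n_folds, n_repeats = config$n_repeats,
    n_replicates = config$n_replicates,
    train_patients = split$train, test_patients = split$test)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(models = models, comparisons = comparisons,
                 split = split, out_dir = config$out_dir))
}
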