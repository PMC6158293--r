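#' Residual-survival horizon
#'
#' @param months One of 2, 6 or 9; one month is 30 days, so horizons are
#'   60, 180 and 270 days.
#' @return List of class `horizon` with `months` and `days`.
#' @export
horizon <- function(months) {
  if (!months %in% c(2, 6, 9)) stop_input("horizon months must be 2, 6 or 9")
  structure(list(months = as.integer(months), days = as.integer(months * 30)),
            class = "horizon")
}

#' Minimum documented history needed to decide pattern occurrence
#'
#' A pattern spanning up to `max_length` visits with up to `max_gap_days`
#' between consecutive matched visits can only be definitively evaluated at
#' a visit with at least `(max_length - 1) * max_gap_days` days of prior
#' documented history (e.g. 3 visits and a 60-day gap require 120 days).
#'
#' @param max_length Maximum pattern length in visits (>= 1).
#' @param max_gap_days Maximum gap in days.
#' @return Required history in days.
#' @export
min_history_required <- function(max_length, max_gap_days) {
  if (max_length < 1) stop_input("max_length must be >= 1")
  (max_length - 1) * max_gap_days
}

#' Residual-survival label of one visit
#'
#' A deceased patient's visit is labeled `le_horizon` when it falls within
#' the horizon of death (boundary inclusive), otherwise `gt_horizon`. A
#' visit of an alive patient is `gt_horizon` when at least a full horizon
#' of follow-up remains before censoring; visits within the horizon of
#' censoring are indeterminable and, under the default policy, excluded
#' (`NA`). `censor_policy = "optimistic"` labels them `gt_horizon`.
#'
#' @param visit_day,outcome_day Day of the visit and of death/censoring.
#' @param deceased Logical.
#' @param horizon A [horizon()] object.
#' @param censor_policy `"exclude"` (default) or `"optimistic"`.
#' @return `"le_horizon"`, `"gt_horizon"`, or `NA` (excluded).
#' @export
label_visit <- function(visit_day, outcome_day, deceased, horizon,
                        censor_policy = c("exclude", "optimistic")) {
  censor_policy <- match.arg(censor_policy)
  if (any(outcome_day < visit_day)) stop_input("outcome day precedes visit day")
  resid <- outcome_day - visit_day
  ifelse(deceased,
         ifelse(resid <= horizon$days, "le_horizon", "gt_horizon"),
         ifelse(resid >= horizon$days, "gt_horizon",
                if (censor_policy == "optimistic") "gt_horizon" else NA_character_))
}

#' Is a pattern observed at (anchored to) a given visit?
#'
#' TRUE iff the pattern's final element is a subset of the anchor visit's
#' items and all earlier elements can be placed at strictly earlier visits
#' with every consecutive matched pair within `max_gap_days`. Features are
#' anchored this way so that no information after the current visit is
#' used.
#'
#' @param sequence One encoded sequence.
#' @param visit_index Index of the anchor visit.
#' @inheritParams contains_pattern
#' @return `TRUE` or `FALSE`.
#' @export
pattern_occurs_at_visit <- function(sequence, visit_index, pattern, max_gap_days) {
  n <- length(sequence$days)
  if (visit_index < 1 || visit_index > n) stop_input("visit_index out of range")
  els <- pattern$elements
  L <- length(els)
  if (!all(els[[L]] %in% sequence$itemsets[[visit_index]])) return(FALSE)
  if (L == 1) return(TRUE)
  if (visit_index == 1) return(FALSE)
  prefix <- temporal_pattern(els[-L])
  trunc <- list(days = sequence$days[seq_len(visit_index - 1)],
                itemsets = sequence$itemsets[seq_len(visit_index - 1)])
  ends <- pattern_match_ends(trunc, prefix, max_gap_days)
  any(sequence$days[visit_index] - sequence$days[ends] <= max_gap_days)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

# Static + dynamic covariate indicator matrix for one record's visit days.
# Age enters as threshold indicators at the decade boundaries 50/60/70,
# recomputed from initial age plus elapsed time at each visit.
covariate_matrix <- function(record, days) {
  age <- record$initial_age + days / 365.25
  eth <- ethnicity_levels[-1]
  loc <- location_levels[-1]
  m <- cbind(
    cov_male = as.numeric(record$sex == "male"),
    cov_mgmt_unmethylated = as.numeric(record$mgmt_status == "unmethylated"),
    cov_lat_right = as.numeric(record$laterality == "right"),
    matrix(rep(as.numeric(record$ethnicity == eth), each = length(days)),
           nrow = length(days),
           dimnames = list(NULL, paste0("cov_eth_", sanitize_name(eth)))),
    matrix(rep(as.numeric(record$tumor_location == loc), each = length(days)),
           nrow = length(days),
           dimnames = list(NULL, paste0("cov_loc_", sanitize_name(loc)))),
    cov_age_ge50 = as.numeric(age >= 50),
    cov_age_ge60 = as.numeric(age >= 60),
    cov_age_ge70 = as.numeric(age >= 70))
  m
}

#' Build the labeled per-visit feature matrix
#'
#' One row per predictable visit: visits with at least
#' [min_history_required()] days of documented prior history (days since
#' the patient's earliest recorded visit) and a determinable
#' residual-survival label. Columns are the mined patterns as visit-anchored
#' 0/1 features plus patient covariate indicators.
#'
#' @param records Patient records.
#' @param patterns List of `temporal_pattern`s (mined with `params`).
#' @param params The [mining_params()] the patterns were mined with.
#' @param horizon A [horizon()] object.
#' @param scheme Discretization scheme fitted on the *training* records.
#' @param representation Volume representation used at encoding time.
#' @param censor_policy Passed to [label_visit()].
#' @return A data frame with `patient_id`, `day`, `label` (factor
#'   `gt_horizon`/`le_horizon`), pattern columns `pat_###` and covariate
#'   columns `cov_*`. Attribute `pattern_map` maps pattern column names to
#'   canonical keys and supports; attribute `scheme_fingerprint` records
#'   the discretization actually applied.
#' @export
build_feature_matrix <- function(records, patterns, params, horizon,
                                 scheme = NULL, representation = "rate_change",
                                 censor_policy = c("exclude", "optimistic")) {
  censor_policy <- match.arg(censor_policy)
  stopifnot(inherits(params, "mining_params"), inherits(horizon, "horizon"))
  sequences <- encode_cohort(records, scheme, representation)
  db <- build_seq_db(sequences)
  w <- gap_windows(db, params$max_gap_days)
  n_pos <- length(db$sid)
  pat_names <- sprintf("pat_%03d", seq_along(patterns))
  P <- matrix(0, nrow = n_pos, ncol = length(patterns),
              dimnames = list(NULL, pat_names))
  for (j in seq_along(patterns)) {
    rows <- pattern_anchor_rows(db, w, patterns[[j]], params$max_gap_days)
    P[rows, j] <- 1
  }
  first_day <- db$day[db$start][db$sid]
  min_hist <- min_history_required(params$max_length, params$max_gap_days)
  outcome <- vapply(records, `[[`, 0, "outcome_day")[db$sid]
  dead <- vapply(records, `[[`, TRUE, "deceased")[db$sid]
  labels <- label_visit(db$day, outcome, dead, horizon, censor_policy)
  keep <- (db$day - first_day) >= min_hist & !is.na(labels)
  covs <- do.call(rbind, lapply(seq_along(records), function(i) {
    covariate_matrix(records[[i]], db$day[db$sid == i])
  }))
  out <- data.frame(
    patient_id = db$patient_ids[db$sid][keep],
    day = db$day[keep],
    label = factor(labels[keep], levels = c("gt_horizon", "le_horizon")),
    P[keep, , drop = FALSE],
    covs[keep, , drop = FALSE],
    check.names = FALSE)
  attr(out, "pattern_map") <- data.frame(
    column = pat_names,
    pattern = vapply(patterns, pattern_key, ""),
    support = vapply(patterns, function(p) p$support, 0))
  attr(out, "scheme_fingerprint") <- if (is.null(scheme)) NA_character_ else scheme_fingerprint(scheme)
  attr(out, "horizon_months") <- horizon$months
  out
}

feature_columns <- function(feat) {
  setdiff(names(feat), c("patient_id", "day", "label"))
}

#' Write a labeled feature matrix with its pattern-definition sidecar
#'
#' The matrix goes to `<path>.csv`; the mapping from pattern columns to
#' canonical pattern definitions goes to `<path>_patterns.json`.
#'
#' @param feat Output of [build_feature_matrix()].
#' @param path Path prefix (no extension).
#' @export
write_feature_matrix <- function(feat, path) {
  utils::write.csv(feat, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(attr(feat, "pattern_map"),
                       paste0(path, "_patterns.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
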