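# Small in-code fixtures shared across the suite.

# One encoded sequence from bare days + itemsets.
seq_of <- function(days, itemsets, id = "p1") {
  list(patient_id = id, days = as.integer(days),
       itemsets = lapply(itemsets, function(x) sort(x)))
}

# Random small sequence database for oracle-equivalence properties.
random_small_db <- function(n_pat = NULL, max_visits = 5, n_items = 5,
                            max_items_per_visit = 3) {
  if (is.null(n_pat)) n_pat <- sample(2:6, 1)
  vocab <- paste0("i", seq_len(n_items))
  lapply(seq_len(n_pat), function(i) {
    nv <- sample(seq_len(max_visits), 1)
    days <- cumsum(c(0L, sample(1:50, nv - 1, replace = TRUE)))
    seq_of(days,
           lapply(seq_len(nv), function(j) {
             sample(vocab, sample(seq_len(max_items_per_visit), 1))
           }),
           id = paste0("p", i))
  })
}

random_mining_params <- function() {
  mining_params(min_support = sample(c(0.2, 0.34, 0.5, 0.67), 1),
                max_gap_days = sample(c(15, 30, 45, 60), 1),
                max_length = sample(1:3, 1),
                max_size = sample(1:2, 1))
}

# A hand-built patient record with controllable visit days and fields.
record_of <- function(id = "P1", days = c(0, 30, 60), kps = NULL,
                      volume = NULL, deceased = TRUE,
                      outcome_day = max(days) + 50, sex = "male",
                      nf = NULL, ons = NULL, ms = NULL,
                      surgery = NULL, radiation = NULL) {
  n <- length(days)
  list(patient_id = id, sex = sex, ethnicity = "White",
       mgmt_status = "unmethylated", tumor_location = "Frontal lobe",
       laterality = "right", initial_age = 55, deceased = deceased,
       outcome_day = outcome_day, carrier = logical(0),
       visits = data.frame(
         day = as.integer(days),
         kps = kps %||% rep(80, n),
         mental_status = ms %||% rep(0L, n),
         neurologic_function = nf %||% rep(1L, n),
         overall_neuro_status = ons %||% c(0L, rep(0L, n - 1)),
         volume_mm3 = volume %||% rep(5000, n),
         surgery = surgery %||% rep(FALSE, n),
         radiation = radiation %||% c(TRUE, rep(FALSE, n - 1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle: conditional likelihood of a 2x2 table with fixed
# margins under odds ratio psi (noncentral hypergeometric), enumerated
# directly over all admissible tables. Used to verify the exact-test
# odds ratio and p-value.
cml_oracle <- function(tab) {
  a <- tab[1, 1]; m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - m2); hi <- min(k, m1)
  support <- lo:hi
  logw <- lchoose(m1, support) + lchoose(m2, k - support)
  cond_p <- function(log_psi) {
    lp <- logw + support * log_psi
    exp(lp - max(lp)) / sum(exp(lp - max(lp)))
  }
  # two-sided Fisher p at psi = 1: total probability of tables as or less likely
  p0 <- cond_p(0)
  p_obs <- p0[support == a]
  p_val <- min(1, sum(p0[p0 <= p_obs * (1 + 1e-7)]))
  # CML estimate: psi maximizing the conditional likelihood of the observed a
  or <- if (a == lo && a == hi) NA_real_
  else if (a == lo) 0
  else if (a == hi) Inf
  else {
    f <- function(lp) log(cond_p(lp)[support == a])
    exp(stats::optimize(f, c(-15, 15), maximum = TRUE, tol = 1e-10)$maximum)
  }
  list(or = or, p_value = p_val)
}

# Default planted pattern + small cohort used in several modeling tests.
test_cohort <- function(seed = 42, n = 60, prevalence = 0.4, hazard = 2) {
  pp <- planted_pattern(temporal_pattern(list("neurologic_function=4")),
                        hazard_log_odds = hazard, prevalence = prevalence)
  generate_cohort(cohort_params(n_patients = n, planted_patterns = list(pp),
                                seed = seed))
}
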