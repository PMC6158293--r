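# patternsurv

Temporal-pattern mining and residual-survival modeling for longitudinal
clinical cohorts, built around the glioblastoma follow-up setting:
patients on standard chemoradiotherapy are seen at roughly monthly visits
where performance status (KPS), mental status, neurologic function,
overall neurologic status, interventions and contrast-enhancing tumor
volume are recorded, and the question at every visit is short-term
prognosis — is *residual survival* (days remaining until death) at most
2, 6 or 9 months?

The package is for biostatisticians and clinical-informatics researchers
who want a fully testable implementation of this modeling pipeline. Since
the clinical data such models are built on is protected, a synthetic
cohort generator with *planted* prognostic patterns stands in for it, so
every stage can be exercised and verified end to end.

## The method

1. **Encoding.** Raw visits become itemsets over a discrete vocabulary
   (`variable=state` items): KPS change states relative to the previous
   visit (with 60 as the significance boundary), neurologic scores,
   interventions, and a tumor-volume representation — raw volume, static
   baseline volume, rate of change (mm³/day), percent change, or
   volumetric response categories — with continuous representations
   discretized into ten equal-frequency states fitted on training
   patients only.

2. **Mining.** `mine_patterns()` discovers all temporal patterns
   (ordered lists of itemsets) with SPADE-family constraints: minimum
   patient-level support *s*, maximum gap *g* days between consecutive
   matched visits, maximum length *l* visits, maximum size *k* events per
   visit. A brute-force enumerator provides an independent oracle; the
   tests require exact equality of pattern sets and supports.

3. **Featurization.** Each pattern becomes a per-visit 0/1 feature via
   anchored matching (final element at the current visit, earlier
   elements before it under the gap rule). Visits need
   `(l − 1) × g` days of documented history (120 days at `l = 3`,
   `g = 60`) to be scored. Labels: within the horizon of death →
   `le_horizon`; alive with a full horizon of follow-up remaining →
   `gt_horizon`; indeterminable visits near censoring are excluded by
   default.

4. **Modeling.** Patient-wise 75/25 split stratified on survival subgroup
   and gender; L1-penalized (LASSO) logistic regression on patterns plus
   covariate indicators; 3×10-fold patient-based cross-validation with
   majority-class down-sampling inside training folds; the
   (mining-parameters, λ) pair with the best mean CV AUC is refit on the
   full training partition. Adjusted odds ratio of a feature is
   exp(coefficient).

5. **Evaluation.** Three approaches are compared on held-out test visits:
   volume thresholding (its threshold sweep is exactly the ROC of volume
   as a score), volume + covariates logistic regression, and the pattern
   model. AUC (Mann–Whitney), average precision, 2000-replicate
   stratified bootstrap CIs, paired bootstrap ΔAUC tests, and Fisher
   exact univariate odds ratios for the top-ranked patterns.

## Worked example

Plant one prognostic pattern — the severe-neurology sentinel event
`neurologic_function=4`, carried by 40% of patients with a +2.0 shift in
the log-odds of short residual survival after its occurrence — and run
the full pipeline:

```r
library(patternsurv)

pp <- planted_pattern(temporal_pattern(list("neurologic_function=4")),
                      hazard_log_odds = 2, prevalence = 0.4)
cohort <- generate_cohort(cohort_params(planted_patterns = list(pp), seed = 1))
cohort_summary(cohort)
#>     n pct_male mean_os mean_visit_gap mean_visits_per_patient pct_deceased
#> 1 304     61.8   566.2           28.4                    16.9         80.6

split <- split_train_test(cohort, seed = 1)
ids   <- vapply(cohort, `[[`, "", "patient_id")
train <- cohort[ids %in% split$train]
test  <- cohort[ids %in% split$test]

model <- select_model(
  data.frame(min_support = 0.3, max_gap_days = 60, max_length = 2, max_size = 1),
  train, horizon(6), seed = 1)
# selected 47 features at lambda 0.004874; CV AUC 0.734

feat  <- build_feature_matrix(train, model$patterns, model$mining, model$horizon,
                              model$scheme, model$representation)
head(rank_patterns(model, feat)$le_horizon[, c("pattern", "support", "adj_or", "uni_or")], 3)
#>                         pattern   support   adj_or   uni_or
#>           neurologic_function=4 0.3991228 4.967482 9.733925
#>        kps=significant_decrease 0.5614035 1.908926 3.229488
#>  kps=decreased -> kps=decreased 0.3333333 1.799666 5.346297

compare_approaches(model, train, test, n_replicates = 2000, seed = 1)$summary
#>                  approach   auc ci_low ci_high average_precision n_visits
#>               volume_only 0.281  0.217   0.349            0.0202     1102
#>    volume_plus_covariates 0.440  0.367   0.510            0.0259     1102
#>  patterns_plus_covariates 0.745  0.709   0.780            0.6108     1027
```

The planted sentinel tops the short-survival ranking (adjusted OR 4.97,
univariate OR 9.7), and the pattern model clearly beats both volume
baselines on held-out test AUC (paired bootstrap p = 1.3e-09 against
volume-only) — as it should, because in this cohort the *only* death
signal is the planted temporal pattern, not volume. The other high-ranked
patterns (significant KPS decline, sustained KPS decrease) emerge from
the generator's near-death decline dynamics rather than planting.

## The analysis workflow

`analysis/` holds the numbered drivers of the full study on the synthetic
cohort; each stage reads the previous stage's artifacts from `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort CSVs + summary
Rscript analysis/02_encode_and_mine.R   # split, discretize, mine patterns
Rscript analysis/03_fit_models.R        # 2-/6-/9-month models, grid + CV
Rscript analysis/04_evaluate.R          # three-approach comparison, rankings
```

`run_pipeline(run_config(...))` performs the same end to end in one call.
The methods vignette (`vignettes/residual-survival-patterns.Rmd`)
documents the model, its assumptions, all tunable parameters, the
synthetic-data design and its limits.

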