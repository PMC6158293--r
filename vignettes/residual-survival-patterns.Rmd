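---
title: "Temporal patterns and residual-survival models: methods"
author: "patternsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal patterns and residual-survival models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternsurv)
```

## The problem

Glioblastoma patients on standard chemoradiotherapy are followed at roughly
monthly clinical visits where performance status (KPS), mental status,
neurologic function, overall neurologic status (Levin-style change scores),
interventions and contrast-enhancing tumor volume are recorded. *Residual
survival* is the number of days remaining from a given visit until death.
This package casts short-term prognosis as a per-visit binary
classification: is residual survival at most 2, 6 or 9 months (60, 180,
270 days; one month is fixed at 30 days)?

The predictive signal is carried by *temporal patterns*: ordered lists of
itemsets over a discrete event vocabulary, mined with SPADE-family
semantics under four constraints — minimum patient-level support, maximum
day gap between consecutive matched visits, maximum pattern length in
visits, and maximum itemset size per visit. A pattern such as

```
neurologic_function=2, overall_neuro_status=0 -> rate_change=[122-371)
```

reads: a visit with moderate symptoms and unchanged overall status,
followed within the gap limit by a visit whose tumor growth rate fell in
the [122, 371) mm^3/day decile.

Because the clinical dataset this design targets is protected health
information, the package ships a synthetic cohort generator that
reproduces the cohort's marginal structure and plants known prognostic
patterns, so every downstream stage is testable end to end.

## Event encoding

The vocabulary follows a fixed state table:

* **surgery / radiation** — `occurred` at visits with the intervention
  (only initiation events are encoded for radiotherapy).
* **KPS** — change states relative to the *immediately preceding* visit:
  `initial` (first observation), `decreased` (dropped, still above 60),
  `significant_decrease` (dropped to at most 60 — literally applied even
  when the previous value was already at or below 60), `increased`
  (rose from above 60), `significant_increase` (rose from at or below
  60), `unchanged`.
* **mental_status** (0–2), **neurologic_function** (0–4),
  **overall_neuro_status** (−2…+2) — recorded states emitted verbatim.
* **tumor volume** — one of five representations: raw volume, per-patient
  baseline volume (the first post-chemoradiation measurement, attached as
  a static decile item at *every* visit so visit-anchored matching can see
  it), rate of change in mm^3/day, percent change, or the volumetric
  response category (`complete` / `partial` at a ≥65% decrease /
  `progression` / `stable`).

Continuous representations are discretized into ten equal-frequency states
whose edges are order statistics of the *training* values; intervals are
right-open `[a, b)` except the last, and test patients are binned with the
training edges unchanged (asserted by fingerprinting the edges). Values
outside the training range fall into the boundary bins. The progression
rule defaults to a ≥40% increase; the printed source table's "≤40%
increase" cannot coexist with "stable: all others", so the inverted
reading is treated as a typographical slip but remains available via
`progression_rule = "le40"`. Volume-derived items are emitted only at
visits with a measurement; rate, percent and response items start at the
second measurement.

## Mining

`mine_patterns()` performs a depth-first search with end-position id-lists:
each lattice node stores the visit positions where the pattern's final
element matches with all earlier elements placed at strictly earlier
visits of the same patient and every consecutive matched pair within the
gap limit. Sequence extensions append a new single-item element; itemset
extensions grow the final element with a lexicographically larger item, so
each pattern is generated exactly once. Support is the fraction of
patients containing the pattern at least once; intervening unmatched
visits are allowed (standard SPADE gap semantics), and no minimum-gap
constraint is imposed. Output is canonically ordered (length, then
lexicographic key), making runs byte-reproducible.

`enumerate_patterns_bruteforce()` is a deliberately independent oracle: it
enumerates, per patient, every gap-valid ordered visit combination and
every admissible itemset subset, and tallies patient-level support
directly. The test suite requires exact set-and-support equality between
the two on hundreds of randomized small databases; the brute-force path is
guarded to at most 10 patients with 6 visits each.

## Featurization and labeling

A pattern becomes a per-visit binary feature through *anchored* matching:
the final element must hold at the current visit, earlier elements at
earlier visits under the gap rule — so no feature ever uses information
after the current visit (a truncation property test enforces this).
Deciding anchored occurrence for a pattern of `max_length` visits with
`max_gap_days` gaps needs `(max_length - 1) * max_gap_days` days of
documented history (120 days at the default 3 × 60); visits with less
history are not scored.

Labels: a deceased patient's visit within the horizon of death (boundary
inclusive) is `le_horizon`, otherwise `gt_horizon`. Visits of alive
patients are `gt_horizon` when a full horizon of follow-up remains before
censoring; closer to censoring the label is indeterminable and such visits
are *excluded* by default (`censor_policy = "optimistic"` reproduces the
literal labeling that treats every non-death-proximal visit as long
survival). Covariates enter as indicator columns: sex, ethnicity, MGMT
methylation, tumor location, laterality, and dynamic age thresholds
(≥50/60/70, recomputed from initial age plus elapsed time at each visit).

## Modeling protocol

* **Split** — patients are divided by overall survival below/above the
  cohort mean (outcome day serves for censored patients), each subgroup
  split 75/25 conserving the male:female ratio, with largest-remainder
  allocation so the overall training fraction is exact; patients are
  wholly in train or test.
* **Cross-validation** — 10-fold, patient-based, repeated 3 times with
  different fold seeds; AUC and average precision averaged over the 30
  validation folds. Folds whose validation part is single-class are
  skipped with a warning.
* **Class imbalance** — the majority class is randomly down-sampled to the
  minority size *inside each training fold and the final training fit
  only*; validation and test data are never balanced.
* **LASSO** — binary features and indicators share a scale, so no
  standardization. The lambda path is 8 logarithmic points from the data's
  lambda-max down to 5% of it; deeper paths mostly admit near-duplicate
  patterns (the pattern lattice is heavily nested, so features are
  strongly correlated) at significant cost and no cross-validated gain.
  The path is scored by the same repeated CV, and the winning
  (mining-configuration, lambda) pair — ties broken by fewer selected
  features, then lexicographic parameter order — is refit on the full
  down-sampled training partition. Adjusted odds ratios are exponentiated
  coefficients.
* **Threshold** — the classification threshold maximizes Youden's J on
  training predictions (median midpoint under ties; 0.5 with a warning in
  degenerate cases). This is the package's own rule, chosen for being
  parameter-free; it is configurable.

## Evaluation

Three approaches are compared per horizon: (1) thresholding raw tumor
volume — sweeping all thresholds traces exactly the ROC of volume as a
score, so its AUC is `auc(volume, labels)` by identity; (2) logistic
regression on volume plus covariates; (3) the temporal-pattern model.
AUCs use the Mann–Whitney formulation (ties half-credit); average
precision is the step-wise area under the precision–recall curve.
Uncertainty comes from 2000-replicate stratified bootstrap percentile
intervals; approach differences use a paired stratified bootstrap of the
AUC difference in normal-deviate form (z = observed difference over the
bootstrap SD, two-sided) — the cited bootstrap-test literature admits
variants, so the variant is named in the output. Univariate pattern
statistics use Fisher's exact test (conditional-ML odds ratio, exact CI,
no continuity correction; zero cells yield 0/Inf estimates with finite
one-sided bounds), with significance at alpha = 0.05. Selected features
are ranked by adjusted OR into a short-survival table (OR > 1,
descending) and a long-survival table (OR < 1, ascending).

## The synthetic cohort

The generator emulates the target cohort's published marginals: 304
patients, 61.8% male (realized by deterministic rounding), 84.5% deceased,
mean overall survival 721.2 days, ~23 scheduled visits ~28.4 days apart
(visit gaps are 1 plus a Poisson draw). Covariate marginals (ethnicity,
MGMT status, tumor location, laterality, initial age 54.6 ± 11.9) follow
the published one-dimensional tables. Mechanisms, where the source reports
only summaries, are the package's own choices:

* **Survival** — baseline log-logistic (shape 1.7, scale solved from the
  mean); deceased status is Bernoulli. Visits are truncated at death, so
  *realized* visits per patient fall below the scheduled mean — the
  configured marginals are the scheduled ones.
* **KPS** — bounded random walk on the 0–100 decile grid with a downward
  drift within 120 days of death; mental status, neurologic function and
  overall neurologic status follow similar near-death-shifted draws, with
  a correlation knob that lets the overall status mirror the KPS change
  direction (no fidelity claim for real inter-variable correlation, which
  the source does not report).
* **Tumor volume** — piecewise-exponential growth (log-normal baseline
  ~6000 mm^3, Gaussian growth rate) with an optional 90-day
  treatment-response dip and multiplicative log-normal noise;
  measurements are present at 85% of visits. Volume is *not* linked to
  death by default, so planted temporal patterns are the only prognostic
  signal — exactly the regime in which the pattern approach should beat
  the volume baselines.
* **Planted patterns** — carriers (a configured prevalence) have the
  pattern's events injected at consecutive visits ending at a
  mid-trajectory anchor; for deceased carriers the probability that
  residual survival from the anchor is at most a 180-day reference
  horizon has its log-odds shifted by the configured hazard. The severe
  states `neurologic_function=4` and `overall_neuro_status=-2` are
  reserved for planting (the background never emits them), so planted
  support equals the carrier fraction up to Bernoulli noise. Only
  directly coded variables can be planted; KPS-change and volume-decile
  states would require inverting the encoder and are rejected with an
  error.

What passing tests on this generator do *not* show: fidelity to the real
cohort's joint distribution, its printed AUCs or odds-ratio tables —
those derive from protected data and are out of reach by design. The
generator demonstrates that the machinery recovers a known signal under
the stated protocol, nothing more.

### A collinearity subtlety

Because sentinel states appear only when planted, a multi-element planted
pattern's anchored feature column can be *identical* to the column of its
final sentinel event alone, and the LASSO's choice among exact duplicates
is arbitrary. The seeded recovery experiments therefore plant a
single-event pattern, whose anchored column strictly dominates every
near-duplicate (any pattern ending in the sentinel fires on a subset of
its anchors, so the planted column carries the largest gradient and enters
the path first). The two-element planted pattern remains in the analysis
scripts as a narrative illustration of temporal structure.

## Numerical choices and problem sizes

Equal-frequency bin edges are order statistics with ties collapsed (and a
warning when fewer bins are achievable); degenerate inputs — a single
distinct value, all-identical scores, single-class folds, empty strata —
produce one-bin schemes, a 0.5 threshold, skipped folds and merged strata
respectively, each with a warning rather than an error. Every random draw
flows from one top-level seed through named substreams, so any artifact is
reproducible from the run manifest.

The shipped experiments use sizes chosen to keep a laptop run comfortable
while preserving the study's conditions: oracle equivalence on hundreds of
randomized ≤10 × ≤6 databases; recovery experiments at the full n = 304
with a one-cell grid (support 0.30, gap 60, length 2, size 1) and the
3 × 10-fold protocol; calibration of the bootstrap test at 100–200 null
trials of 150 visits with 500 replicates; the analysis scripts mine at
support 0.30–0.35 with length 2 and size 2. Widening the grid toward
length-3/size-4 combinations is supported and simply costs more time.

## Known limitations

* The generator's inter-variable dependence is a single knob, not a fit to
  data; absolute AUCs on synthetic cohorts are not comparable to those on
  clinical data.
* Support counting is gap-constrained (matching the miner); a study that
  counted unconstrained subsequence containment would report slightly
  higher supports for multi-element patterns.
* The exact supplementary parameter grid of the original study design is
  not public; the default grid is a documented stand-in.
* No time-to-event modeling: the task is per-visit binary classification
  by design, and survival-curve outputs are out of scope.
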