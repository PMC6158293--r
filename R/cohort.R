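#' Parameters of the synthetic glioblastoma cohort generator
#'
#' Defaults reproduce the marginal structure of the cohort the workflow is
#' designed for: 304 patients, a mean of 23.3 visits per patient roughly
#' 28.4 days apart, 61.8% male, 84.5% deceased, mean overall survival
#' 721.2 days.
#'
#' @param n_patients Number of patients (>= 2).
#' @param mean_visit_gap_days Mean days between consecutive visits (> 0).
#' @param visits_per_patient_mean Mean number of scheduled visits (> 0).
#' @param frac_male Proportion male; realized deterministically as
#'   `round(n_patients * frac_male)` male patients.
#' @param frac_deceased Proportion deceased (Bernoulli per patient).
#' @param mean_overall_survival_days Mean of the baseline log-logistic
#'   overall-survival distribution.
#' @param os_shape Shape of the baseline log-logistic (> 1 so the mean exists).
#' @param planted_patterns List of [planted_pattern()] objects.
#' @param neuro_kps_correlation In [0, 1]: probability that the overall
#'   neurologic status mirrors the direction of the KPS change at a visit
#'   (no fidelity claim is made for real inter-variable correlation).
#' @param volume_measurement_prob Probability a visit has a tumor volume
#'   measurement.
#' @param seed Integer seed; identical seed and parameters give
#'   byte-identical cohorts.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 304,
                          mean_visit_gap_days = 28.4,
                          visits_per_patient_mean = 23.3,
                          frac_male = 0.618,
                          frac_deceased = 0.845,
                          mean_overall_survival_days = 721.2,
                          os_shape = 1.7,
                          planted_patterns = list(),
                          neuro_kps_correlation = 0.5,
                          volume_measurement_prob = 0.85,
                          seed = 1L) {
  assert_that(is.numeric(n_patients) && n_patients >= 2, "n_patients must be >= 2")
  assert_that(mean_visit_gap_days > 0, "mean_visit_gap_days must be > 0")
  assert_that(visits_per_patient_mean > 0, "visits_per_patient_mean must be > 0")
  for (p in c(frac_male, frac_deceased, neuro_kps_correlation, volume_measurement_prob)) {
    assert_that(is_proportion(p), "proportions must lie in [0, 1]")
  }
  assert_that(mean_overall_survival_days > 0, "mean_overall_survival_days must be > 0")
  assert_that(os_shape > 1, "os_shape must exceed 1")
  for (pp in planted_patterns) {
    assert_that(inherits(pp, "planted_pattern"), "planted_patterns must be planted_pattern objects")
  }
  structure(list(n_patients = as.integer(n_patients),
                 mean_visit_gap_days = mean_visit_gap_days,
                 visits_per_patient_mean = visits_per_patient_mean,
                 frac_male = frac_male, frac_deceased = frac_deceased,
                 mean_overall_survival_days = mean_overall_survival_days,
                 os_shape = os_shape,
                 planted_patterns = planted_patterns,
                 neuro_kps_correlation = neuro_kps_correlation,
                 volume_measurement_prob = volume_measurement_prob,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' A temporal pattern planted into the synthetic cohort
#'
#' Carriers (a `prevalence` fraction of patients) have the pattern's events
#' injected at consecutive visits ending at a mid-trajectory anchor; for
#' deceased carriers the log-odds of short residual survival after the
#' anchor are shifted by `hazard_log_odds`, giving the downstream feature
#' selection a recoverable prognostic signal. Only directly coded
#' variables (mental_status, neurologic_function, overall_neuro_status,
#' surgery, radiation) can be planted; the severe states
#' `neurologic_function=4` and `overall_neuro_status=-2` are never emitted
#' by the background process, so planted support equals the carrier
#' fraction up to Bernoulli noise.
#'
#' @param pattern A [temporal_pattern()] (or list of character itemsets).
#' @param hazard_log_odds Shift in the log-odds that residual survival from
#'   the anchor visit is at most the 180-day reference horizon.
#' @param prevalence Proportion of patients in whom the pattern is injected.
#' @return A list of class `planted_pattern`.
#' @export
planted_pattern <- function(pattern, hazard_log_odds = 1.5, prevalence = 0.35) {
  if (!inherits(pattern, "temporal_pattern")) pattern <- temporal_pattern(pattern)
  assert_that(is_proportion(prevalence), "prevalence must lie in [0, 1]")
  plantable <- c("mental_status", "neurologic_function", "overall_neuro_status",
                 "surgery", "radiation")
  for (el in pattern$elements) {
    vars <- sub("=.*$", "", el)
    if (!all(vars %in% plantable)) {
      stop_input(sprintf(
        "planted items must use directly coded variables (%s); got: %s",
        paste(plantable, collapse = ", "), paste(el, collapse = ", ")))
    }
  }
  structure(list(pattern = pattern, hazard_log_odds = hazard_log_odds,
                 prevalence = prevalence),
            class = "planted_pattern")
}

# Log-logistic helpers (scale a, shape b): S(t) = 1 / (1 + (t/a)^b).
llog_scale_for_mean <- function(mean, shape) {
  mean * sin(pi / shape) / (pi / shape)
}
rllog <- function(n, scale, shape) {
  u <- stats::runif(n)
  scale * (u / (1 - u))^(1 / shape)
}
pllog <- function(q, scale, shape) {
  x <- (q / scale)^shape
  x / (1 + x)
}
qllog <- function(p, scale, shape) {
  scale * (p / (1 - p))^(1 / shape)
}

ethnicity_levels <- c("White", "Hispanic", "Asian", "Middle eastern",
                      "Black", "Other", "Unknown")
ethnicity_probs <- c(0.714, 0.079, 0.056, 0.013, 0.007, 0.049, 0.082)
location_levels <- c("Frontal lobe", "Temporal lobe", "Parietal lobe",
                     "Occipital lobe", "Thalamus", "Corpus callosum",
                     "Cerebellum", "Pineal gland", "Midbrain")
location_probs <- c(0.375, 0.299, 0.250, 0.059, 0.026, 0.013, 0.003, 0.003, 0.003)

#' Generate a synthetic longitudinal glioblastoma cohort
#'
#' Produces patient records with the statistical structure the analysis
#' assumes: covariate marginals of a standard chemoradiotherapy GBM cohort,
#' integer visit-day grids from a shifted-Poisson gap process, bounded
#' random-walk KPS with downward drift near death, piecewise-exponential
#' tumor volume trajectories with multiplicative log-normal noise and
#' optional treatment-response dips, a baseline log-logistic overall
#' survival, and planted prognostic temporal patterns that shift residual
#' survival after their anchor visit.
#'
#' @param params A [cohort_params()] object.
#' @return A list of patient records (class `cohort`). Each record carries
#'   `patient_id`, covariates, `deceased`, `outcome_day` (death day, or
#'   censoring day for alive patients), a logical `carrier` vector over the
#'   planted patterns, and a `visits` data frame with columns `day`, `kps`,
#'   `mental_status`, `neurologic_function`, `overall_neuro_status`,
#'   `volume_mm3`, `surgery`, `radiation`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(params$seed, {
    n <- params$n_patients
    n_male <- round(n * params$frac_male)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    ethnicity <- sample(ethnicity_levels, n, replace = TRUE, prob = ethnicity_probs)
    mgmt <- sample(c("methylated", "unmethylated"), n, replace = TRUE,
                   prob = c(0.339, 0.661))
    location <- sample(location_levels, n, replace = TRUE,
                       prob = location_probs / sum(location_probs))
    laterality <- sample(c("right", "left"), n, replace = TRUE,
                         prob = c(0.533, 0.490) / (0.533 + 0.490))
    age <- round(pmin(90, pmax(18, stats::rnorm(n, 54.6, 11.9))), 1)
    deceased <- stats::rbinom(n, 1, params$frac_deceased) == 1
    os_scale <- llog_scale_for_mean(params$mean_overall_survival_days, params$os_shape)
    # residual-survival distribution from a mid-trajectory anchor visit
    res_scale <- llog_scale_for_mean(300, 1.6)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      n_visits <- 1L + stats::rpois(1, max(0, params$visits_per_patient_mean - 1))
      gaps <- 1L + stats::rpois(max(0, n_visits - 1), max(0, params$mean_visit_gap_days - 1))
      days <- as.integer(c(0, cumsum(gaps)))
      carrier <- vapply(params$planted_patterns, function(pp) {
        stats::runif(1) < pp$prevalence
      }, TRUE)
      # injection anchors: consecutive visits ending at a mid/late visit
      inject <- list()  # per planted pattern: visit indices of its elements
      anchor_day <- -Inf
      hazard <- 0
      for (k in seq_along(params$planted_patterns)) {
        if (!isTRUE(carrier[k])) next
        pp <- params$planted_patterns[[k]]
        L <- length(pp$pattern$elements)
        lo <- max(L, min(n_visits, ceiling(n_visits / 3)))
        a <- if (lo >= n_visits) n_visits else sample(lo:n_visits, 1)
        if (a < L) { carrier[k] <- FALSE; next }
        inject[[k]] <- (a - L + 1L):a
        anchor_day <- max(anchor_day, days[a])
        hazard <- hazard + pp$hazard_log_odds
      }
      if (deceased[i]) {
        if (is.finite(anchor_day)) {
          p0 <- pllog(180, res_scale, 1.6)
          p_short <- stats::plogis(stats::qlogis(p0) + hazard)
          u <- stats::runif(1)
          r <- if (stats::runif(1) < p_short) {
            qllog(u * p0, res_scale, 1.6)            # residual <= 180 d
          } else {
            qllog(p0 + u * (1 - p0), res_scale, 1.6) # residual > 180 d
          }
          death_day <- anchor_day + max(5, r)
        } else {
          death_day <- max(60, rllog(1, os_scale, params$os_shape))
        }
        keep <- days < death_day
        keep[1] <- TRUE
        days <- days[keep]
        inject <- lapply(inject, function(ix) ix[ix <= length(days)])
        outcome_day <- as.integer(ceiling(death_day))
      } else {
        outcome_day <- as.integer(days[length(days)] +
          1L + stats::rpois(1, max(0, params$mean_visit_gap_days - 1)))
      }
      nv <- length(days)
      near_death <- deceased[i] & (outcome_day - days) <= 120
      # KPS: bounded random walk on the decile grid, downward drift near death
      kps <- numeric(nv)
      kps[1] <- sample(c(70, 80, 90), 1, prob = c(0.2, 0.5, 0.3))
      for (v in seq_len(nv)[-1]) {
        pr <- if (near_death[v]) c(0.45, 0.50, 0.05) else c(0.15, 0.70, 0.15)
        kps[v] <- min(100, max(10, kps[v - 1] + sample(c(-10, 0, 10), 1, prob = pr)))
      }
      ms <- vapply(seq_len(nv), function(v) {
        pr <- if (near_death[v]) c(0.45, 0.35, 0.20) else c(0.80, 0.15, 0.05)
        sample(0:2, 1, prob = pr)
      }, 0L)
      nf <- integer(nv)
      nf[1] <- sample(0:1, 1, prob = c(0.6, 0.4))
      for (v in seq_len(nv)[-1]) {
        pr <- if (near_death[v]) c(0.05, 0.55, 0.40) else c(0.10, 0.75, 0.15)
        nf[v] <- min(3L, max(0L, nf[v - 1] + sample(c(-1L, 0L, 1L), 1, prob = pr)))
      }
      ons <- integer(nv)
      for (v in seq_len(nv)[-1]) {
        if (stats::runif(1) < params$neuro_kps_correlation) {
          ons[v] <- as.integer(sign(kps[v] - kps[v - 1]))
        } else {
          ons[v] <- sample(c(-1L, 0L, 1L, 2L), 1, prob = c(0.15, 0.60, 0.20, 0.05))
        }
      }
      # piecewise-exponential volume with optional treatment-response dip
      v0 <- stats::rlnorm(1, log(6000), 0.8)
      growth <- stats::rnorm(1, 0.006, 0.004)
      rate <- rep(growth, nv)
      if (stats::runif(1) < 0.35 && nv > 3) {
        s <- sample(2:(nv - 1), 1)
        dip_until <- days[s] + 90
        rate[days >= days[s] & days <= dip_until] <- -0.010
      }
      log_v <- log(v0) + cumsum(c(0, rate[-1] * diff(days)))
      vol <- exp(log_v + stats::rnorm(nv, 0, 0.12))
      vol[stats::runif(nv) > params$volume_measurement_prob] <- NA_real_
      if (is.na(vol[1])) vol[1] <- exp(log_v[1])
      surg <- stats::runif(nv) < 0.01
      surg[1] <- FALSE
      rad <- stats::runif(nv) < 0.005
      rad[1] <- TRUE
      # plant pattern events (overrides the background draws)
      for (k in seq_along(inject)) {
        ix <- inject[[k]]
        if (is.null(ix) || length(ix) == 0) next
        els <- params$planted_patterns[[k]]$pattern$elements
        for (j in seq_along(ix)) {
          if (j > length(els)) break
          for (item in els[[j]]) {
            kv <- strsplit(item, "=", fixed = TRUE)[[1]]
            val <- kv[2]
            switch(kv[1],
              mental_status = { ms[ix[j]] <- as.integer(val) },
              neurologic_function = { nf[ix[j]] <- as.integer(val) },
              overall_neuro_status = { ons[ix[j]] <- as.integer(sub("^\\+", "", val)) },
              surgery = { surg[ix[j]] <- TRUE },
              radiation = { rad[ix[j]] <- TRUE })
          }
        }
      }
      records[[i]] <- list(
        patient_id = sprintf("P%04d", i),
        sex = sex[i], ethnicity = ethnicity[i], mgmt_status = mgmt[i],
        tumor_location = location[i], laterality = laterality[i],
        initial_age = age[i], deceased = deceased[i],
        outcome_day = outcome_day,
        carrier = carrier,
        visits = data.frame(day = days, kps = kps, mental_status = ms,
                            neurologic_function = nf,
                            overall_neuro_status = ons,
                            volume_mm3 = round(vol, 1),
                            surgery = surg, radiation = rad))
    }
    structure(records, class = "cohort", params = params)
  })
}

#' Summary statistics of a cohort
#'
#' @param records A cohort (list of patient records).
#' @return One-row data frame with `n`, `pct_male` (1-decimal percent),
#'   `mean_os` (mean outcome day), `mean_visit_gap`, `mean_visits_per_patient`
#'   and `pct_deceased`.
#' @export
cohort_summary <- function(records) {
  if (length(records) == 0) stop_input("empty cohort")
  gaps <- unlist(lapply(records, function(r) diff(r$visits$day)))
  data.frame(
    n = length(records),
    pct_male = round(100 * mean(vapply(records, function(r) r$sex == "male", TRUE)), 1),
    mean_os = round(mean(vapply(records, `[[`, 0, "outcome_day")), 1),
    mean_visit_gap = round(mean(gaps), 1),
    mean_visits_per_patient = round(mean(vapply(records, function(r) nrow(r$visits), 0)), 1),
    pct_deceased = round(100 * mean(vapply(records, `[[`, TRUE, "deceased")), 1))
}

#' Write/read a cohort as two CSV files
#'
#' `patients.csv` holds one row per patient (covariates and outcome);
#' `visits.csv` holds one row per visit. Missing values are empty fields.
#'
#' @param records A cohort.
#' @param dir Directory to write into (created if needed).
#' @return Invisibly, the directory (`write_cohort`) or the cohort
#'   (`read_cohort`).
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patients <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, sex = r$sex, ethnicity = r$ethnicity,
               mgmt_status = r$mgmt_status, tumor_location = r$tumor_location,
               laterality = r$laterality, initial_age = r$initial_age,
               status = if (r$deceased) "deceased" else "alive",
               outcome_day = r$outcome_day)
  }))
  visits <- do.call(rbind, lapply(records, function(r) {
    cbind(patient_id = r$patient_id, r$visits)
  }))
  utils::write.csv(patients, file.path(dir, "patients.csv"), row.names = FALSE, na = "")
  utils::write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"),
                              colClasses = c(patient_id = "character"))
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            colClasses = c(patient_id = "character"))
  visits$surgery <- as.logical(visits$surgery)
  visits$radiation <- as.logical(visits$radiation)
  records <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    vs <- visits[visits$patient_id == p$patient_id,
                 setdiff(names(visits), "patient_id"), drop = FALSE]
    rownames(vs) <- NULL
    list(patient_id = p$patient_id, sex = p$sex, ethnicity = p$ethnicity,
         mgmt_status = p$mgmt_status, tumor_location = p$tumor_location,
         laterality = p$laterality, initial_age = p$initial_age,
         deceased = p$status == "deceased", outcome_day = p$outcome_day,
         carrier = logical(0), visits = vs)
  })
  structure(records, class = "cohort")
}
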