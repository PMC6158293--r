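#' Discrete state of a Karnofsky performance status (KPS) observation
#'
#' Classifies the current KPS relative to the immediately preceding visit's
#' KPS into one of six states. KPS is scored 0-100 in steps of 10; 60 marks
#' the boundary between ordinary and significant functional decline.
#'
#' @param previous_kps KPS at the previous visit, or `NA` if this is the
#'   first observed KPS.
#' @param current_kps KPS at the current visit (0-100).
#' @return One of `"initial"`, `"decreased"`, `"significant_decrease"`,
#'   `"increased"`, `"significant_increase"`, `"unchanged"`.
#' @examples
#' kps_state(NA, 90)  # "initial"
#' kps_state(90, 80)  # "decreased"
#' kps_state(80, 60)  # "significant_decrease"
#' @export
kps_state <- function(previous_kps, current_kps) {
  check_kps <- function(x, what) {
    if (!is.na(x) && (!is.numeric(x) || x < 0 || x > 100)) {
      stop_input(sprintf("%s KPS must be in [0, 100], got %s", what, x))
    }
  }
  if (is.null(previous_kps)) previous_kps <- NA_real_
  check_kps(previous_kps, "previous")
  if (is.na(current_kps)) stop_input("current KPS must not be missing")
  check_kps(current_kps, "current")
  if (is.na(previous_kps)) return("initial")
  if (current_kps < previous_kps) {
    if (current_kps <= 60) "significant_decrease" else "decreased"
  } else if (current_kps > previous_kps) {
    if (previous_kps <= 60) "significant_increase" else "increased"
  } else {
    "unchanged"
  }
}

kps_states <- c("initial", "decreased", "significant_decrease",
                "increased", "significant_increase", "unchanged")

#' Rate of tumor volume change between two sequential measurements
#'
#' @param v1,v2 Tumor volumes in mm^3 at the earlier and later visit.
#' @param d1,d2 Day offsets of the two visits; `d2` must exceed `d1`.
#' @return Rate of change in mm^3/day, `(v2 - v1) / (d2 - d1)`.
#' @export
volume_rate_change <- function(v1, v2, d1, d2) {
  if (any(d2 <= d1)) {
    stop_input("invalid interval: second measurement day must exceed the first")
  }
  (v2 - v1) / (d2 - d1)
}

#' Tumor volume gain implied by a sustained rate of change
#'
#' A rate of 371 mm^3/day held over a 60-day inter-visit gap implies a gain
#' of 22.26 cm^3.
#'
#' @param rate_mm3_per_day Rate of volume change in mm^3/day.
#' @param gap_days Length of the interval in days (> 0).
#' @return Implied volume change in cm^3.
#' @export
implied_volume_gain <- function(rate_mm3_per_day, gap_days) {
  if (any(gap_days <= 0)) stop_input("gap_days must be positive")
  rate_mm3_per_day * gap_days / 1000
}

#' Percent change between two tumor volumes
#'
#' @param v1 Earlier volume in mm^3 (> 0).
#' @param v2 Later volume in mm^3.
#' @return `100 * (v2 - v1) / v1`, in percent.
#' @export
percent_change <- function(v1, v2) {
  if (any(v1 <= 0)) stop_input("percent change undefined for non-positive baseline volume")
  100 * (v2 - v1) / v1
}

#' Volumetric response category of consecutive tumor volumes
#'
#' Volumetric analogue of the RANO response criteria comparing the current
#' volume to the previous one: `complete` (resolution of all enhancement),
#' `partial` (>= 65% decrease), `progression` (>= 40% increase under the
#' default rule), `stable` (all others). Categories are mutually exclusive
#' with precedence complete > partial > progression > stable.
#'
#' @param v_prev,v_curr Previous and current volumes in mm^3 (>= 0).
#' @param progression_rule `"ge40"` (default) classifies increases of at
#'   least 40% as progression; `"le40"` classifies positive increases of at
#'   most 40% as progression (a literal reading of an inconsistent printed
#'   rule, kept switchable).
#' @return Character vector over `{"complete","partial","progression","stable"}`.
#' @export
rano_response <- function(v_prev, v_curr, progression_rule = c("ge40", "le40")) {
  progression_rule <- match.arg(progression_rule)
  if (any(v_prev < 0) || any(v_curr < 0)) stop_input("volumes must be non-negative")
  n <- max(length(v_prev), length(v_curr))
  v_prev <- rep_len(v_prev, n); v_curr <- rep_len(v_curr, n)
  out <- rep("stable", n)
  pct <- ifelse(v_prev > 0, 100 * (v_curr - v_prev) / v_prev, NA_real_)
  prog <- if (progression_rule == "ge40") {
    (!is.na(pct) & pct >= 40) | (v_prev == 0 & v_curr > 0)
  } else {
    (!is.na(pct) & pct > 0 & pct <= 40)
  }
  out[prog] <- "progression"
  out[!is.na(pct) & pct <= -65] <- "partial"
  out[v_curr == 0] <- "complete"
  out
}

#' Fit an equal-frequency discretization scheme
#'
#' Bin edges are order statistics of the training values so that bin counts
#' differ by at most one when values are distinct. Intervals are right-open
#' `[a, b)` except the last, labelled in the style `"[122-371)"`. With fewer
#' distinct values than bins the scheme collapses to the achievable number
#' of bins (with a warning).
#'
#' @param values Numeric training values (fitted on training patients only).
#' @param k Requested number of bins.
#' @param variable Name of the variable the scheme discretizes.
#' @return An object of class `discretization_scheme` with fields
#'   `variable`, `inner_edges`, `bounds`, `labels`, `k`.
#' @export
fit_equal_frequency_bins <- function(values, k = 10, variable = "value") {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop_input("no finite values to discretize")
  if (k < 1) stop_input("k must be >= 1")
  v <- sort(values)
  n <- length(v)
  inner <- if (k > 1) v[pmin(n, floor(n * seq_len(k - 1) / k) + 1)] else numeric(0)
  inner <- unique(inner[inner > v[1]])
  k_eff <- length(inner) + 1L
  if (k_eff < k) {
    warning(sprintf("only %d distinct bin(s) achievable for '%s' (requested %d)",
                    k_eff, variable, k))
  }
  bounds <- c(v[1], inner, v[n])
  fmt <- function(x) formatC(signif(x, 4), format = "fg", digits = 4)
  labels <- character(k_eff)
  if (k_eff == 1) {
    labels <- sprintf("[%s-%s]", fmt(bounds[1]), fmt(bounds[2]))
  } else {
    for (i in seq_len(k_eff)) {
      close <- if (i == k_eff) "]" else ")"
      labels[i] <- sprintf("[%s-%s%s", fmt(bounds[i]), fmt(bounds[i + 1]), close)
    }
  }
  structure(list(variable = variable, inner_edges = inner, bounds = bounds,
                 labels = labels, k = k_eff),
            class = "discretization_scheme")
}

#' Bin index of values under a fitted discretization scheme
#'
#' Values outside the training range fall into the first or last bin.
#' @param scheme A `discretization_scheme`.
#' @param x Numeric values.
#' @return Integer bin indices in `1..scheme$k`.
#' @export
bin_index <- function(scheme, x) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  findInterval(x, scheme$inner_edges) + 1L
}

#' @rdname bin_index
#' @return `bin_label` returns the interval label of each value's bin.
#' @export
bin_label <- function(scheme, x) scheme$labels[bin_index(scheme, x)]

# Stable fingerprint of a scheme's edges; used to assert that the scheme
# applied to test patients is bit-identical to the one fitted on training.
scheme_fingerprint <- function(scheme) {
  paste(c(scheme$variable, sprintf("%.17g", scheme$bounds)), collapse = "|")
}

volume_representations <- c("volume", "baseline", "rate_change",
                            "percent_change", "rano")

# Continuous values of one volume representation, pooled across records.
# Used to fit the equal-frequency scheme on the training partition.
representation_values <- function(records, representation) {
  vals <- lapply(records, function(rec) {
    vs <- rec$visits
    m <- !is.na(vs$volume_mm3)
    v <- vs$volume_mm3[m]; d <- vs$day[m]
    switch(representation,
      volume = v,
      baseline = if (length(v)) v[1] else numeric(0),
      rate_change = if (length(v) >= 2) diff(v) / diff(d) else numeric(0),
      percent_change = {
        if (length(v) >= 2 && all(v[-length(v)] > 0)) {
          100 * diff(v) / v[-length(v)]
        } else if (length(v) >= 2) {
          keep <- v[-length(v)] > 0
          (100 * diff(v) / v[-length(v)])[keep]
        } else numeric(0)
      },
      stop_input(sprintf("unknown representation '%s'", representation)))
  })
  unlist(vals, use.names = FALSE)
}

#' Fit the discretization scheme for a tumor-volume representation
#'
#' Continuous representations (`volume`, `baseline`, `rate_change`,
#' `percent_change`) are discretized into `k` equal-frequency states on the
#' training records; the categorical `rano` representation needs no scheme.
#'
#' @param records Training patient records (see [generate_cohort()]).
#' @param representation One of [volume_representations].
#' @param k Number of equal-frequency states (default 10).
#' @return A `discretization_scheme`, or `NULL` for `"rano"`.
#' @export
fit_volume_scheme <- function(records, representation, k = 10) {
  representation <- match.arg(representation, volume_representations)
  if (representation == "rano") return(NULL)
  vals <- representation_values(records, representation)
  fit_equal_frequency_bins(vals, k = k, variable = representation)
}

#' Encode one patient record into a sequence of visit itemsets
#'
#' Converts raw per-visit measurements into the discrete event vocabulary
#' consumed by the pattern miner: one itemset ("transaction") per clinical
#' visit, items formatted `variable=state`. The first visit emits the
#' initial-KPS item; rate/percent/RANO volume items appear from the second
#' volume measurement onward; the static baseline-volume item is attached
#' at every visit so visit-anchored matching can see it.
#'
#' @param record A patient record (list with `patient_id` and a `visits`
#'   data frame; see [generate_cohort()]).
#' @param scheme Discretization scheme for the chosen representation
#'   (from [fit_volume_scheme()]); ignored for `"rano"`.
#' @param representation One of [volume_representations].
#' @return A list with `patient_id`, integer vector `days`, and `itemsets`
#'   (a list of sorted character vectors, one per visit).
#' @export
encode_patient <- function(record, scheme = NULL, representation = "rate_change") {
  representation <- match.arg(representation, volume_representations)
  vs <- record$visits
  if (is.unsorted(vs$day, strictly = TRUE)) {
    stop_input(sprintf("visits of patient %s are not strictly sorted by day",
                       record$patient_id))
  }
  if (representation != "rano" && is.null(scheme)) {
    stop_input("a fitted discretization scheme is required for continuous representations")
  }
  n <- nrow(vs)
  itemsets <- vector("list", n)
  prev_kps <- NA_real_
  meas_idx <- which(!is.na(vs$volume_mm3))
  baseline_item <- if (representation == "baseline" && length(meas_idx)) {
    paste0("baseline_volume=", bin_label(scheme, vs$volume_mm3[meas_idx[1]]))
  } else NULL
  prev_meas <- NA_integer_
  for (i in seq_len(n)) {
    items <- character(0)
    if (isTRUE(vs$surgery[i] > 0)) items <- c(items, "surgery=occurred")
    if (isTRUE(vs$radiation[i] > 0)) items <- c(items, "radiation=occurred")
    if (!is.na(vs$kps[i])) {
      items <- c(items, paste0("kps=", kps_state(prev_kps, vs$kps[i])))
      prev_kps <- vs$kps[i]
    }
    if (!is.na(vs$mental_status[i])) {
      items <- c(items, paste0("mental_status=", vs$mental_status[i]))
    }
    if (!is.na(vs$neurologic_function[i])) {
      items <- c(items, paste0("neurologic_function=", vs$neurologic_function[i]))
    }
    if (!is.na(vs$overall_neuro_status[i])) {
      s <- vs$overall_neuro_status[i]
      lab <- if (s > 0) sprintf("+%d", s) else sprintf("%d", s)
      items <- c(items, paste0("overall_neuro_status=", lab))
    }
    if (!is.na(vs$volume_mm3[i])) {
      v <- vs$volume_mm3[i]
      if (representation == "volume") {
        items <- c(items, paste0("volume=", bin_label(scheme, v)))
      } else if (!is.na(prev_meas) && representation != "baseline") {
        v0 <- vs$volume_mm3[prev_meas]; d0 <- vs$day[prev_meas]
        items <- c(items, switch(representation,
          rate_change = paste0("rate_change=",
                               bin_label(scheme, volume_rate_change(v0, v, d0, vs$day[i]))),
          percent_change = if (v0 > 0) {
            paste0("percent_change=", bin_label(scheme, percent_change(v0, v)))
          } else character(0),
          rano = paste0("rano=", rano_response(v0, v))))
      }
      prev_meas <- i
    }
    if (!is.null(baseline_item)) items <- c(items, baseline_item)
    itemsets[[i]] <- sort(unique(items))
  }
  keep <- lengths(itemsets) > 0
  list(patient_id = record$patient_id,
       days = as.integer(vs$day[keep]),
       itemsets = itemsets[keep])
}

#' Encode a list of patient records
#'
#' @param records List of patient records.
#' @inheritParams encode_patient
#' @return List of encoded sequences (see [encode_patient()]).
#' @export
encode_cohort <- function(records, scheme = NULL, representation = "rate_change") {
  lapply(records, encode_patient, scheme = scheme, representation = representation)
}

#' Write/read encoded sequences as tab-separated text
#'
#' One line per visit: `patient_id<TAB>day<TAB>item1;item2;...`.
#' This plain-text form is the canonical input to the miner.
#'
#' @param sequences Encoded sequences (see [encode_cohort()]).
#' @param path File path.
#' @export
write_sequences <- function(sequences, path) {
  lines <- unlist(lapply(sequences, function(s) {
    sprintf("%s\t%d\t%s", s$patient_id, s$days,
            vapply(s$itemsets, paste, "", collapse = ";"))
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sequences
#' @return `read_sequences` returns the list-of-sequences structure.
#' @export
read_sequences <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("patient_id", "day", "items"),
                           colClasses = c("character", "integer", "character"))
  ids <- unique(tab$patient_id)
  lapply(ids, function(id) {
    rows <- tab[tab$patient_id == id, , drop = FALSE]
    list(patient_id = id, days = rows$day,
         itemsets = strsplit(rows$items, ";", fixed = TRUE))
  })
}
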