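#' Construct a temporal pattern
#'
#' A temporal pattern is an ordered, non-empty list of itemsets: events that
#' co-occur at one visit form an element, and elements are matched to
#' strictly later visits subject to a maximum day gap between consecutive
#' matched visits.
#'
#' @param elements List of non-empty character vectors of items
#'   (`variable=state`); items within an element are stored sorted.
#' @param support Patient-level support in (0, 1], or `NA` if not computed.
#' @return An object of class `temporal_pattern`.
#' @export
temporal_pattern <- function(elements, support = NA_real_) {
  if (is.character(elements)) elements <- list(elements)
  if (length(elements) == 0 || any(lengths(elements) == 0)) {
    stop_input("pattern elements must be a non-empty list of non-empty itemsets")
  }
  structure(list(elements = lapply(elements, function(e) sort(unique(e))),
                 support = support),
            class = "temporal_pattern")
}

#' @export
format.temporal_pattern <- function(x, ...) pattern_key(x)

#' @export
print.temporal_pattern <- function(x, ...) {
  cat(sprintf("<temporal_pattern> %s (support %s)\n", pattern_key(x),
              if (is.na(x$support)) "?" else sprintf("%.3f", x$support)))
  invisible(x)
}

#' Canonical string key of a temporal pattern
#'
#' Items within an element are comma-separated in sorted order; elements are
#' joined by `" -> "`. Used for canonical ordering and de-duplication.
#' @param pattern A `temporal_pattern` (or bare element list).
#' @return A single string.
#' @export
pattern_key <- function(pattern) {
  els <- if (inherits(pattern, "temporal_pattern")) pattern$elements else pattern
  paste(vapply(els, function(e) paste(sort(e), collapse = ","), ""),
        collapse = " -> ")
}

#' @rdname pattern_key
#' @param key A key produced by `pattern_key`.
#' @return `parse_pattern_key` returns the `temporal_pattern`.
#' @export
parse_pattern_key <- function(key, support = NA_real_) {
  els <- strsplit(strsplit(key, " -> ", fixed = TRUE)[[1]], ",", fixed = TRUE)
  temporal_pattern(els, support)
}

# Canonical output order: by number of elements, then lexicographic key.
sort_patterns <- function(patterns) {
  if (length(patterns) == 0) return(patterns)
  keys <- vapply(patterns, pattern_key, "")
  lens <- vapply(patterns, function(p) length(p$elements), 0L)
  patterns[order(lens, keys, method = "radix")]
}

#' Mining constraints
#'
#' @param min_support Minimum patient-level support in (0, 1].
#' @param max_gap_days Maximum days between consecutive matched visits.
#' @param max_length Maximum number of visits (elements) in a pattern.
#' @param max_size Maximum number of events per visit (itemset size).
#' @return A list of class `mining_params`.
#' @export
mining_params <- function(min_support = 0.3, max_gap_days = 60,
                          max_length = 3, max_size = 3) {
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop_input("min_support must be in (0, 1]")
  }
  if (max_gap_days < 1 || max_length < 1 || max_size < 1) {
    stop_input("max_gap_days, max_length and max_size must be >= 1")
  }
  structure(list(min_support = min_support,
                 max_gap_days = as.integer(max_gap_days),
                 max_length = as.integer(max_length),
                 max_size = as.integer(max_size)),
            class = "mining_params")
}

# Indexed form of an encoded sequence database: one row per visit position,
# with a dense item-occurrence matrix for vectorized id-list joins.
build_seq_db <- function(sequences) {
  if (length(sequences) == 0) stop_input("empty sequence database")
  n_visits <- vapply(sequences, function(s) length(s$days), 0L)
  sid <- rep(seq_along(sequences), n_visits)
  day <- unlist(lapply(sequences, `[[`, "days"), use.names = FALSE)
  itemsets <- unlist(lapply(sequences, `[[`, "itemsets"), recursive = FALSE)
  vocab <- sort(unique(unlist(itemsets, use.names = FALSE)))
  occ <- matrix(FALSE, nrow = length(sid), ncol = length(vocab))
  cols <- match(unlist(itemsets, use.names = FALSE), vocab)
  occ[cbind(rep(seq_along(sid), lengths(itemsets)), cols)] <- TRUE
  start <- c(1L, cumsum(n_visits)[-length(n_visits)] + 1L)
  list(n_patients = length(sequences),
       patient_ids = vapply(sequences, function(s) as.character(s$patient_id), ""),
       sid = sid, day = day, vid = unlist(lapply(n_visits, seq_len)),
       vocab = vocab, occ = occ,
       start = start, end = cumsum(n_visits))
}

# Row index of the last visit of the same patient reachable from each row
# within `gap` days (the S-extension window is rows r+1 .. w[r]).
gap_windows <- function(db, gap) {
  w <- integer(length(db$sid))
  for (s in seq_len(db$n_patients)) {
    a <- db$start[s]; b <- db$end[s]
    ds <- db$day[a:b]
    w[a:b] <- a - 1L + findInterval(ds + gap, ds)
  }
  w
}

# Rows reachable from any of `rows` within the gap window (candidate visits
# for the next pattern element).
reach_rows <- function(rows, w) {
  lens <- w[rows] - rows
  keep <- lens > 0L
  if (!any(keep)) return(integer(0))
  r <- rows[keep]; l <- lens[keep]
  sort.int(unique(rep(r, l) + sequence(l)))
}

#' Mine frequent temporal patterns under SPADE-family constraints
#'
#' Depth-first search over the pattern lattice using end-position id-lists:
#' each node stores the visit positions where the pattern's last element
#' matches with all earlier elements placed at strictly earlier visits of
#' the same patient and every consecutive matched pair within
#' `max_gap_days`. Sequence extensions append a new single-item element;
#' itemset extensions grow the last element with a lexicographically larger
#' item, so each pattern is generated exactly once. Support is
#' patient-level: the fraction of patients whose sequence contains the
#' pattern at least once.
#'
#' @param sequences Encoded sequences (see [encode_cohort()]).
#' @param params A [mining_params()] object.
#' @return List of `temporal_pattern` objects with supports attached, in
#'   canonical order (by length, then lexicographic element order).
#' @export
mine_patterns <- function(sequences, params) {
  stopifnot(inherits(params, "mining_params"))
  db <- build_seq_db(sequences)
  w <- gap_windows(db, params$max_gap_days)
  n <- db$n_patients
  min_count <- params$min_support * n - 1e-9
  n_items <- length(db$vocab)
  res_keys <- character(0)
  res_elements <- list()
  res_support <- numeric(0)

  support_of <- function(rows) length(unique(db$sid[rows]))

  # elements: list of integer vectors (vocab indices); rows: end positions
  visit <- function(elements, rows, j_last, sup_count) {
    els <- lapply(elements, function(e) db$vocab[e])
    res_keys[[length(res_keys) + 1L]] <<- pattern_key(els)
    res_elements[[length(res_elements) + 1L]] <<- els
    res_support[[length(res_support) + 1L]] <<- sup_count / n
    last <- elements[[length(elements)]]
    if (length(last) < params$max_size && j_last < n_items) {
      for (j in (j_last + 1L):n_items) {
        nr <- rows[db$occ[rows, j]]
        if (length(nr) && support_of(nr) >= min_count) {
          el2 <- elements
          el2[[length(el2)]] <- c(last, j)
          visit(el2, nr, j, support_of(nr))
        }
      }
    }
    if (length(elements) < params$max_length) {
      reach <- reach_rows(rows, w)
      if (length(reach)) {
        sub <- db$occ[reach, , drop = FALSE]
        for (j in seq_len(n_items)) {
          nr <- reach[sub[, j]]
          if (length(nr)) {
            sc <- support_of(nr)
            if (sc >= min_count) visit(c(elements, list(j)), nr, j, sc)
          }
        }
      }
    }
  }

  for (j in seq_len(n_items)) {
    rows <- which(db$occ[, j])
    if (length(rows)) {
      sc <- support_of(rows)
      if (sc >= min_count) visit(list(j), rows, j, sc)
    }
  }
  out <- Map(function(e, s) temporal_pattern(e, s), res_elements, res_support)
  sort_patterns(out)
}

#' Exhaustive brute-force pattern enumeration (verification oracle)
#'
#' Independently of the id-list miner, enumerates for every patient all
#' gap-valid ordered visit combinations up to `max_length` and all itemset
#' subsets up to `max_size`, collects the distinct patterns each patient
#' contains, and tallies patient-level support. Guarded to small databases.
#'
#' @inheritParams mine_patterns
#' @return Same structure and canonical order as [mine_patterns()].
#' @export
enumerate_patterns_bruteforce <- function(sequences, params) {
  stopifnot(inherits(params, "mining_params"))
  if (length(sequences) == 0) stop_input("empty sequence database")
  if (length(sequences) > 10 ||
      any(vapply(sequences, function(s) length(s$days), 0L) > 6)) {
    stop_input("brute-force enumeration is guarded to <= 10 patients x <= 6 visits")
  }
  per_patient <- lapply(sequences, function(s) {
    n <- length(s$days)
    # all non-empty subsets (size <= max_size) of each visit's items, as keys
    subset_keys <- lapply(s$itemsets, function(items) {
      items <- sort(items)
      ks <- character(0)
      for (m in seq_len(min(length(items), params$max_size))) {
        cmb <- utils::combn(items, m)
        ks <- c(ks, apply(cmb, 2, paste, collapse = ","))
      }
      ks
    })
    combos <- list()
    extend <- function(prefix) {
      if (length(prefix) > 0) combos[[length(combos) + 1L]] <<- prefix
      if (length(prefix) == params$max_length) return()
      last <- if (length(prefix)) prefix[length(prefix)] else 0L
      nxt <- if (last < n) (last + 1L):n else integer(0)
      for (i in nxt) {
        if (last == 0L || s$days[i] - s$days[last] <= params$max_gap_days) {
          extend(c(prefix, i))
        }
      }
    }
    extend(integer(0))
    keys <- unlist(lapply(combos, function(idx) {
      parts <- subset_keys[idx]
      grid <- do.call(expand.grid, c(parts, list(stringsAsFactors = FALSE)))
      do.call(paste, c(unname(grid), list(sep = " -> ")))
    }), use.names = FALSE)
    unique(keys)
  })
  counts <- table(unlist(per_patient, use.names = FALSE))
  n <- length(sequences)
  keep <- counts >= params$min_support * n - 1e-9
  pats <- Map(function(k, c) parse_pattern_key(k, c / n),
              names(counts)[keep], as.integer(counts[keep]))
  sort_patterns(unname(pats))
}

#' Does a patient's sequence contain a temporal pattern?
#'
#' Forward dynamic program over visits: element i+1 may match any visit
#' strictly after a visit matching elements 1..i and within `max_gap_days`
#' of it; unmatched intervening visits are permitted.
#'
#' @param sequence One encoded sequence (see [encode_patient()]).
#' @param pattern A `temporal_pattern`.
#' @param max_gap_days Maximum days between consecutive matched visits.
#' @return `TRUE` or `FALSE`.
#' @export
contains_pattern <- function(sequence, pattern, max_gap_days) {
  length(pattern_match_ends(sequence, pattern, max_gap_days)) > 0
}

# Visit indices at which the full pattern can end (all elements placed).
pattern_match_ends <- function(sequence, pattern, max_gap_days) {
  stopifnot(inherits(pattern, "temporal_pattern"))
  days <- sequence$days
  itemsets <- sequence$itemsets
  n <- length(days)
  prev <- integer(0)
  for (k in seq_along(pattern$elements)) {
    el <- pattern$elements[[k]]
    cur <- integer(0)
    for (v in seq_len(n)) {
      if (!all(el %in% itemsets[[v]])) next
      if (k == 1) {
        cur <- c(cur, v)
      } else if (any(prev < v & days[v] - days[prev] <= max_gap_days)) {
        cur <- c(cur, v)
      }
    }
    if (length(cur) == 0) return(integer(0))
    prev <- cur
  }
  prev
}

#' Patient-level support of a pattern in a sequence database
#'
#' Each patient counts at most once, regardless of how many times the
#' pattern occurs in their history.
#'
#' @param pattern A `temporal_pattern`.
#' @param sequences List of encoded sequences.
#' @inheritParams contains_pattern
#' @return Proportion of patients containing the pattern.
#' @export
pattern_support <- function(pattern, sequences, max_gap_days) {
  if (length(sequences) == 0) stop_input("empty sequence database")
  mean(vapply(sequences, contains_pattern, TRUE,
              pattern = pattern, max_gap_days = max_gap_days))
}

# Vectorized anchored matching over a whole database: returns the row
# indices (into db positions) where the pattern's final element matches
# with all earlier elements placed under the gap rule. Used to build
# feature matrices efficiently; oracle-checked against
# pattern_occurs_at_visit() in the tests.
pattern_anchor_rows <- function(db, w, pattern, max_gap_days) {
  els <- pattern$elements
  cols <- lapply(els, function(e) match(e, db$vocab))
  if (any(vapply(cols, anyNA, TRUE))) return(integer(0))
  rows_for <- function(cand, cl) {
    if (length(cand) == 0) return(integer(0))
    m <- db$occ[cand, cl, drop = FALSE]
    cand[rowSums(m) == length(cl)]
  }
  rows <- rows_for(seq_along(db$sid), cols[[1]])
  for (k in seq_along(els)[-1]) {
    if (length(rows) == 0) return(integer(0))
    rows <- rows_for(reach_rows(rows, w), cols[[k]])
  }
  rows
}
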