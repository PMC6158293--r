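test_that("KPS states follow the visit-to-visit change rules", {
  expect_equal(kps_state(NA, 90), "initial")
  expect_equal(kps_state(90, 80), "decreased")
  expect_equal(kps_state(80, 60), "significant_decrease")
  expect_equal(kps_state(50, 40), "significant_decrease")
  expect_equal(kps_state(60, 70), "significant_increase")
  expect_equal(kps_state(70, 80), "increased")
  expect_equal(kps_state(70, 70), "unchanged")
  expect_error(kps_state(80, 110), "KPS")
  expect_error(kps_state(-10, 80), "KPS")
})

test_that("every legal KPS pair maps to exactly one state", {
  grid <- seq(0, 100, by = 10)
  for (prev in c(NA, grid)) {
    for (cur in grid) {
      s <- kps_state(prev, cur)
      expect_true(s %in% c("initial", "decreased", "significant_decrease",
                           "increased", "significant_increase", "unchanged"))
    }
  }
})

test_that("volume arithmetic: rate, implied gain, percent change", {
  expect_equal(volume_rate_change(1000, 2000, 0, 10), 100)
  expect_equal(volume_rate_change(500, 500, 3, 13), 0)
  expect_error(volume_rate_change(1000, 2000, 10, 10), "interval")
  expect_equal(implied_volume_gain(371, 60), 22.26)
  expect_equal(implied_volume_gain(0, 60), 0)
  expect_equal(implied_volume_gain(100, 30), 3)
  expect_error(implied_volume_gain(100, 0), "positive")
  expect_equal(percent_change(100, 150), 50)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(10000, 3000), -70)
  expect_error(percent_change(0, 100), "undefined")
})

test_that("volumetric response categories are exclusive with the right precedence", {
  expect_equal(rano_response(10000, 0), "complete")
  expect_equal(rano_response(10000, 3000), "partial")
  expect_equal(rano_response(10000, 15000), "progression")
  expect_equal(rano_response(10000, 11000), "stable")
  expect_equal(rano_response(0, 0), "complete")
  expect_equal(rano_response(0, 500), "progression")
  expect_error(rano_response(-1, 10), "non-negative")
  # the literal inverted rule stays available behind the flag
  expect_equal(rano_response(10000, 11000, progression_rule = "le40"), "progression")
  expect_equal(rano_response(10000, 15000, progression_rule = "le40"), "stable")
  # fuzz: exactly one category for any non-negative pair
  set.seed(1)
  for (i in 1:200) {
    r <- rano_response(runif(1, 0, 2e4), runif(1, 0, 2e4))
    expect_length(r, 1)
    expect_true(r %in% c("complete", "partial", "progression", "stable"))
  }
})

test_that("equal-frequency binning yields balanced bins on distinct values", {
  sch <- fit_equal_frequency_bins(1:100, k = 10)
  expect_equal(sch$k, 10)
  expect_equal(as.vector(table(bin_index(sch, 1:100))), rep(10, 10))

  set.seed(7)
  z <- rnorm(1000)
  sch2 <- fit_equal_frequency_bins(z, k = 10)
  expect_equal(as.vector(table(bin_index(sch2, z))), rep(100, 10))

  expect_warning(deg <- fit_equal_frequency_bins(rep(3, 50), k = 10), "achievable")
  expect_equal(deg$k, 1)
  # out-of-range values clamp into the first/last bin
  expect_equal(bin_index(sch, -5), 1L)
  expect_equal(bin_index(sch, 1e6), 10L)
})

test_that("bin labels use right-open interval notation", {
  sch <- fit_equal_frequency_bins(1:100, k = 4)
  expect_match(sch$labels[1], "^\\[.*\\)$")
  expect_match(sch$labels[4], "^\\[.*\\]$")
})

test_that("patient encoding emits the expected items", {
  rec <- record_of(days = 0, volume = 5000)
  sch <- fit_equal_frequency_bins(c(-50, 0, 50, 100, 150), k = 5,
                                  variable = "rate_change")
  enc <- encode_patient(rec, sch, "rate_change")
  expect_length(enc$days, 1)
  expect_true("kps=initial" %in% enc$itemsets[[1]])

  rec2 <- record_of(days = c(0, 10), volume = c(1000, 2000))
  enc2 <- encode_patient(rec2, sch, "rate_change")
  expect_true(paste0("rate_change=", bin_label(sch, 100)) %in% enc2$itemsets[[2]])
  expect_false(any(grepl("^rate_change=", enc2$itemsets[[1]])))

  rec3 <- record_of(days = c(0, 30), surgery = c(FALSE, TRUE))
  enc3 <- encode_patient(rec3, sch, "rate_change")
  expect_true("surgery=occurred" %in% enc3$itemsets[[2]])
  expect_true("radiation=occurred" %in% enc3$itemsets[[1]])

  unsorted <- record_of(days = c(0, 30, 20))
  expect_error(encode_patient(unsorted, sch, "rate_change"), "sorted")
})

test_that("baseline-volume item is static and attached at every visit", {
  rec <- record_of(days = c(0, 30, 60), volume = c(4000, 9000, 2000))
  sch <- fit_equal_frequency_bins(c(1000, 3000, 5000, 8000, 12000), k = 5,
                                  variable = "baseline")
  enc <- encode_patient(rec, sch, "baseline")
  item <- paste0("baseline_volume=", bin_label(sch, 4000))
  for (v in 1:3) expect_true(item %in% enc$itemsets[[v]])
})

test_that("decoding items back to (variable, state) pairs and re-encoding is the identity", {
  co <- test_cohort(seed = 5, n = 12)
  sch <- fit_volume_scheme(co, "rate_change")
  seqs <- encode_cohort(co, sch, "rate_change")
  for (s in seqs[1:4]) {
    for (items in s$itemsets) {
      pairs <- strsplit(items, "=", fixed = TRUE)
      rebuilt <- sort(vapply(pairs, function(p) paste(p[1], p[2], sep = "="), ""))
      expect_identical(rebuilt, items)
      expect_false(any(duplicated(vapply(pairs, `[[`, "", 1))))
    }
  }
})

test_that("schemes fitted on training patients apply unchanged to test patients", {
  co <- test_cohort(seed = 9, n = 30)
  train <- co[1:20]; test <- co[21:30]
  sch <- fit_volume_scheme(train, "rate_change")
  fp_before <- patternsurv:::scheme_fingerprint(sch)
  invisible(encode_cohort(test, sch, "rate_change"))
  expect_identical(patternsurv:::scheme_fingerprint(sch), fp_before)
  sch_test <- fit_volume_scheme(test, "rate_change")
  expect_false(identical(patternsurv:::scheme_fingerprint(sch_test), fp_before))
})

test_that("sequence files round-trip through the TSV form", {
  co <- test_cohort(seed = 3, n = 6)
  sch <- fit_volume_scheme(co, "rate_change")
  seqs <- encode_cohort(co, sch, "rate_change")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequences(seqs, path)
  back <- read_sequences(path)
  expect_equal(length(back), length(seqs))
  for (i in seq_along(seqs)) {
    expect_identical(back[[i]]$days, seqs[[i]]$days)
    expect_identical(back[[i]]$itemsets, seqs[[i]]$itemsets)
  }
})
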