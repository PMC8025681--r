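test_that("read_registry round-trips well-formed files and maps columns", {
  recs <- toy_records(3, ae90 = c(0, 1, 0), bmi = c(28, 31, 24))
  path <- write_cohort_csv(recs)
  cohort <- read_registry(path)
  expect_equal(nrow(cohort), 3)
  expect_equal(cohort$ae90, c(0, 1, 0))
  expect_equal(cohort$bmi, c(28, 31, 24))
  expect_s3_class(cohort$sex, "factor")

  # configurable column mapping
  renamed <- dplyr::rename(recs, adverse_90d = ae90)
  path2 <- write_cohort_csv(renamed)
  expect_error(read_registry(path2), class = "fp_config_error")
  mapped <- read_registry(path2, col_map = c(ae90 = "adverse_90d"))
  expect_equal(mapped$ae90, c(0, 1, 0))
})

test_that("read_registry rejects invalid values with the offending row", {
  recs <- toy_records(3)
  recs$ae90[2] <- 2
  path <- write_cohort_csv(recs)
  expect_error(read_registry(path), regexp = "row.*2", class = "fp_validation_error")

  recs <- toy_records(3)
  recs$age[3] <- -1
  expect_error(read_registry(write_cohort_csv(recs)),
               regexp = "age", class = "fp_validation_error")

  recs <- toy_records(2)
  recs$sex[1] <- "unknown"
  expect_error(read_registry(write_cohort_csv(recs)),
               class = "fp_validation_error")
})

test_that("missing BMI/ASA tokens parse as missing values, not zeros", {
  recs <- toy_records(12)
  recs$bmi[c(3, 7)] <- NA
  recs$asa[5] <- NA
  cohort <- read_registry(write_cohort_csv(recs, na = ""))
  expect_equal(nrow(cohort), 12)
  expect_equal(sum(is.na(cohort$bmi)), 2)
  expect_equal(sum(is.na(cohort$asa)), 1)
  # "NA" token also parses as missing by default
  cohort2 <- read_registry(write_cohort_csv(recs, na = "NA"))
  expect_equal(sum(is.na(cohort2$bmi)), 2)
})

test_that("simultaneous bilateral pairs collapse to one surgery with OR outcomes", {
  base <- toy_records(4, surgeon_id = c("S01", "S01", "S02", "S02"),
                      ae90 = c(0, 0, 1, 0), reop2y = c(0, 0, 0, 0))
  cohort <- with_bilateral_pairs(base, pair_idx = c(1, 3),
                                 second_ae90 = c(1, 0), second_reop2y = c(0, 1))
  out <- collapse_bilateral(cohort)
  expect_equal(nrow(out), 4)
  expect_equal(out$ae90[out$record_id == "R0001"], 1)   # OR of (0, 1)
  expect_equal(out$ae90[out$record_id == "R0003"], 1)   # OR of (1, 0)
  expect_equal(out$reop2y[out$record_id == "R0003"], 1) # OR of (0, 1)
  # number of distinct surgeons is never changed by the collapse
  expect_setequal(unique(out$surgeon_id), unique(cohort$surgeon_id))
})

test_that("collapse_bilateral is the identity without pairs and is idempotent", {
  cohort <- toy_cohort(5, ae90 = c(1, 0, 0, 1, 0))
  out <- collapse_bilateral(cohort)
  expect_equal(cohort_data(out), cohort_data(cohort))
  prov <- provenance(out)
  expect_equal(prov$n_removed[prov$filter == "collapse_bilateral"], 0L)

  paired <- with_bilateral_pairs(toy_records(6), pair_idx = c(2, 5))
  once <- collapse_bilateral(paired)
  twice <- collapse_bilateral(once)
  expect_equal(cohort_data(twice), cohort_data(once))
})

test_that("collapse_bilateral matches the expected count on a paired fixture", {
  # n base records plus k second sides in: n records out
  set.seed(42)
  base <- toy_records(300, surgeon_id = sample(sprintf("S%02d", 1:10), 300,
                                               replace = TRUE))
  cohort <- with_bilateral_pairs(base, pair_idx = sample(300, 7))
  expect_equal(nrow(cohort), 307)
  expect_equal(nrow(collapse_bilateral(cohort)), 300)
})

test_that("malformed bilateral groups are rejected", {
  recs <- toy_records(3, bilateral_group = "B001")
  expect_error(as_cohort(recs), regexp = "at most 2",
               class = "fp_validation_error")

  # two sides naming different patients
  recs <- toy_records(2, patient_id = c("P1", "P2"), bilateral_group = "B001")
  expect_error(as_cohort(recs), class = "fp_validation_error")

  # two sides naming different surgeons
  recs <- toy_records(2, patient_id = "P1", surgeon_id = c("S01", "S02"),
                      bilateral_group = "B001")
  expect_error(collapse_bilateral(as_cohort(recs)),
               regexp = "different surgeons", class = "fp_validation_error")
})

test_that("complete-case filtering removes exactly the incomplete records", {
  recs <- toy_records(3)
  recs$bmi[2] <- NA
  cohort <- as_cohort(recs)
  out <- complete_case_filter(cohort, "bmi")
  expect_equal(out$record_id, c("R0001", "R0003"))
  # empty requirement set is the identity
  expect_equal(nrow(complete_case_filter(cohort, character(0))), 3)
  expect_error(complete_case_filter(cohort, "shoe_size"),
               class = "fp_config_error")
})

test_that("complete-case counts match a brute-force tally on a noisy fixture", {
  set.seed(7)
  recs <- toy_records(1000)
  recs$bmi[runif(1000) < 0.06] <- NA
  recs$asa[runif(1000) < 0.03] <- NA
  cohort <- as_cohort(recs)
  expected_n <- sum(!is.na(recs$bmi) & !is.na(recs$asa))
  out <- complete_case_filter(cohort, c("bmi", "asa"))
  expect_equal(nrow(out), expected_n)
  prov <- provenance(out)
  expect_equal(prov$n_removed[nrow(prov)], 1000L - expected_n)
})

test_that("complete-case filtering composes and is idempotent", {
  set.seed(8)
  recs <- toy_records(400)
  recs$bmi[runif(400) < 0.1] <- NA
  recs$asa[runif(400) < 0.1] <- NA
  cohort <- as_cohort(recs)
  joint <- complete_case_filter(cohort, c("bmi", "asa"))
  seq2 <- complete_case_filter(complete_case_filter(cohort, "bmi"), "asa")
  expect_equal(joint$record_id, seq2$record_id)
  again <- complete_case_filter(joint, c("bmi", "asa"))
  expect_equal(nrow(again), nrow(joint))
})

test_that("stratification partitions by year, disjoint and exhaustive", {
  cohort <- toy_cohort(3, year = c(2011L, 2011L, 2013L))
  strata <- stratify(cohort)
  expect_named(strata, c("2011", "2013"))
  expect_equal(vapply(strata, nrow, integer(1)), c("2011" = 2L, "2013" = 1L))
  expect_setequal(unlist(lapply(strata, function(s) s$record_id)),
                  cohort$record_id)

  pooled <- stratify(cohort, by_year = FALSE)
  expect_named(pooled, "all_years")
  expect_equal(nrow(pooled$all_years), 3)
})

test_that("per-year stratum sizes equal direct tallies on a generated fixture", {
  reg <- generate_cohort(synthetic_config(n_surgeons = 20, years = 2011:2016,
                                          seed = 3))
  strata <- stratify(reg$cohort)
  tally <- table(reg$cohort$year)
  expect_equal(vapply(strata, nrow, integer(1)),
               setNames(as.integer(tally), names(tally)))
})

test_that("volume filter honours strict and non-strict thresholds", {
  counts <- c(S01 = 5, S02 = 10, S03 = 11, S04 = 27)
  recs <- toy_records(sum(counts),
                      surgeon_id = rep(names(counts), counts))
  cohort <- as_cohort(recs)

  strict <- volume_filter(cohort, 10, strict = TRUE)
  expect_setequal(unique(strict$surgeon_id), c("S03", "S04"))
  expect_equal(nrow(strict), 11 + 27)

  # a surgeon with exactly 10 surgeries is excluded under ">" but kept under ">="
  at_least <- volume_filter(cohort, 10, strict = FALSE)
  expect_setequal(unique(at_least$surgeon_id), c("S02", "S03", "S04"))

  expect_equal(nrow(volume_filter(cohort, 0, strict = FALSE)), nrow(cohort))
  twice <- volume_filter(strict, 10, strict = TRUE)
  expect_equal(nrow(twice), nrow(strict))
})

test_that("provenance counts reconcile across a filter chain", {
  set.seed(9)
  recs <- toy_records(500, surgeon_id = sample(sprintf("S%02d", 1:12), 500,
                                               replace = TRUE))
  recs$bmi[runif(500) < 0.08] <- NA
  cohort <- with_bilateral_pairs(as_cohort(recs), pair_idx = c(10, 20, 30))
  out <- cohort |>
    collapse_bilateral() |>
    complete_case_filter("bmi") |>
    volume_filter(10, strict = TRUE)
  prov <- provenance(out)
  expect_equal(prov$n_in - prov$n_removed, prov$n_out)
  expect_equal(prov$n_in[-1], prov$n_out[-nrow(prov)])
  expect_equal(prov$n_out[nrow(prov)], nrow(out))
})

test_that("summaries survive a write/read round trip", {
  reg <- generate_cohort(synthetic_config(n_surgeons = 10, years = 2011L,
                                          seed = 4, miss_bmi = 0, miss_asa = 0))
  model <- fit_risk_model(reg$cohort, "ae90")
  summ <- summarize_surgeons(reg$cohort, model)
  path <- tempfile(fileext = ".csv")
  write_summaries(summ, path)
  back <- read_summaries(path)
  expect_equal(nrow(back), nrow(summ))
  expect_equal(back$observed, summ$observed)
  expect_equal(back$expected, summ$expected, tolerance = 1e-12)
  expect_equal(back$standardized_prop, summ$standardized_prop, tolerance = 1e-12)

  expect_error(write_summaries(summ[0, ], path), class = "fp_config_error")

  many <- dplyr::bind_rows(lapply(1:208, function(i) {
    dplyr::mutate(summ[1, ], surgeon_id = sprintf("S%03d", i))
  }))
  path2 <- tempfile(fileext = ".csv")
  write_summaries(many, path2)
  expect_equal(nrow(read_summaries(path2)), 208)
})
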