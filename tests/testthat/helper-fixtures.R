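# Builders for small in-code fixtures. All randomness is seeded by callers.

toy_records <- function(n = 1, record_id = NULL, patient_id = NULL,
                        surgeon_id = "S01", hospital_id = "H01", year = 2011L,
                        age = 69, sex = "female", bmi = 28, asa = "II",
                        diagnosis = "primary_OA", grade = "specialist",
                        bilateral_group = NA_character_,
                        ae90 = 0, reop2y = 0) {
  tibble::tibble(
    record_id = record_id %||% sprintf("R%04d", seq_len(n)),
    patient_id = patient_id %||% sprintf("P%04d", seq_len(n)),
    surgeon_id = surgeon_id, hospital_id = hospital_id, year = year,
    age = age, sex = sex, bmi = bmi, asa = asa,
    diagnosis = diagnosis, grade = grade,
    bilateral_group = bilateral_group,
    ae90 = ae90, reop2y = reop2y
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_cohort <- function(...) as_cohort(toy_records(...))

# A cohort with simultaneous bilateral pairs appended: each pair duplicates
# a base record under a shared group token (second side outcomes settable).
with_bilateral_pairs <- function(records, pair_idx, second_ae90 = NULL,
                                 second_reop2y = NULL) {
  tokens <- sprintf("B%03d", seq_along(pair_idx))
  records$bilateral_group[pair_idx] <- tokens
  second <- records[pair_idx, ]
  second$record_id <- paste0(second$record_id, "b")
  if (!is.null(second_ae90)) second$ae90 <- second_ae90
  if (!is.null(second_reop2y)) second$reop2y <- second_reop2y
  as_cohort(dplyr::bind_rows(records, second))
}

write_cohort_csv <- function(records, path = tempfile(fileext = ".csv"),
                             na = "") {
  readr::write_csv(records, path, na = na)
  path
}

# Independent oracle for the upper Wilson bound: numeric inversion of the
# score test. The upper bound u >= p solves (u - p)^2 * n = z^2 * u * (1 - u).
wilson_upper_oracle <- function(p, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  if (p >= 1) return(1)
  h <- function(q) (q - p)^2 * n - z^2 * q * (1 - q)
  uniroot(h, c(p + 1e-12, 1), tol = 1e-13)$root
}

# Vectorized bisection version of the same oracle, for dense grids.
wilson_upper_oracle_grid <- function(p, n, level, iter = 80) {
  z <- qnorm(1 - (1 - level) / 2)
  h <- function(q) (q - p)^2 * n - z^2 * q * (1 - q)
  lo <- p
  hi <- rep(1, length(p))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    pos <- h(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

# In-control study configuration used across tests.
null_study_config <- function(seed, years = 2011L, ...) {
  synthetic_config(n_surgeons = 208, years = years, volume_mean = 27,
                   volume_sd = 17, surgeon_effect_sd = 0, seed = seed, ...)
}

# Column data of a cohort, with filter provenance and class attributes
# stripped, for value-only comparisons.
cohort_data <- function(x) {
  out <- as.list(tibble::as_tibble(x))
  attributes(out) <- list(names = names(out))
  out
}
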