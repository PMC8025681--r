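#' @keywords internal
#' Canonical column set of a surgery record.
registry_columns <- function() {
  c("record_id", "patient_id", "surgeon_id", "hospital_id", "year",
    "age", "sex", "bmi", "asa", "diagnosis", "grade",
    "bilateral_group", "ae90", "reop2y")
}

#' Covariate names eligible for complete-case filtering
#' @keywords internal
registry_covariates <- function() {
  c("age", "sex", "bmi", "asa", "diagnosis", "grade")
}

outcome_names <- function() c("ae90", "reop2y")

#' Coerce a data frame to a validated surgery cohort
#'
#' A cohort is a tibble with one row per primary surgery and a `provenance`
#' attribute logging every inclusion filter applied to it (filter name, rows
#' in, rows out, rows removed). All downstream verbs
#' ([collapse_bilateral()], [complete_case_filter()], [volume_filter()],
#' [stratify()]) preserve and extend the provenance log.
#'
#' Validation enforces the record invariants: unique `record_id`, outcomes in
#' \{0, 1\} (or missing), `age > 0`, categorical levels among the supported
#' sets, and well-formed simultaneous-bilateral groups (at most two records
#' per group, sharing `patient_id` and `year`).
#'
#' @param x A data frame with the registry columns (`record_id`,
#'   `patient_id`, `surgeon_id`, `hospital_id`, `year`, `age`, `sex`, `bmi`,
#'   `asa`, `diagnosis`, `grade`, `bilateral_group`, `ae90`, `reop2y`).
#'   `bilateral_group` may be absent (treated as all-`NA`).
#' @return A tibble of class `fp_cohort` with a `provenance` attribute.
#' @seealso [provenance()], [read_registry()]
#' @export
as_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"bilateral_group" %in% names(x)) x$bilateral_group <- NA_character_
  missing_cols <- setdiff(registry_columns(), names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
      class = "fp_config_error"
    )
  }
  x <- x[registry_columns()]
  x$year <- as.integer(x$year)
  x$sex <- as_registry_factor(x$sex, c("female", "male"), "sex")
  x$asa <- as_registry_factor(x$asa, c("I", "II", "III", "IV"), "asa")
  x$diagnosis <- as_registry_factor(x$diagnosis, c("primary_OA", "secondary_OA"), "diagnosis")
  x$grade <- as_registry_factor(x$grade, c("specialist", "trainee"), "grade")
  validate_cohort(x)
  new_cohort(x, provenance = empty_provenance(nrow(x)))
}

as_registry_factor <- function(v, levels, what) {
  v <- as.character(v)
  bad <- which(!is.na(v) & !v %in% levels)
  if (length(bad) > 0) {
    abort(
      paste0("invalid ", what, " value(s) ", paste(unique(v[bad]), collapse = ", "),
             " on row(s) ", paste(head(bad, 5), collapse = ", ")),
      class = "fp_validation_error"
    )
  }
  factor(v, levels = levels)
}

validate_cohort <- function(x) {
  dup <- duplicated(x$record_id)
  if (any(dup)) {
    abort(paste0("duplicate record_id on row(s) ",
                 paste(head(which(dup), 5), collapse = ", ")),
          class = "fp_validation_error")
  }
  for (oc in outcome_names()) {
    bad <- which(!is.na(x[[oc]]) & !x[[oc]] %in% c(0, 1))
    if (length(bad) > 0) {
      abort(paste0(oc, " outside {0,1} on row(s) ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "fp_validation_error")
    }
  }
  bad_age <- which(!is.na(x$age) & x$age <= 0)
  if (length(bad_age) > 0) {
    abort(paste0("age <= 0 on row(s) ", paste(head(bad_age, 5), collapse = ", ")),
          class = "fp_validation_error")
  }
  validate_bilateral_groups(x)
  invisible(x)
}

validate_bilateral_groups <- function(x) {
  grouped <- x[!is.na(x$bilateral_group), ]
  if (nrow(grouped) == 0) return(invisible(x))
  by_group <- split(seq_len(nrow(grouped)), grouped$bilateral_group)
  for (g in names(by_group)) {
    idx <- by_group[[g]]
    if (length(idx) > 2) {
      abort(paste0("bilateral group '", g, "' has ", length(idx),
                   " records (at most 2 allowed)"),
            class = "fp_validation_error")
    }
    if (length(idx) == 2) {
      pa <- grouped$patient_id[idx]
      yr <- grouped$year[idx]
      if (pa[1] != pa[2] || yr[1] != yr[2]) {
        abort(paste0("bilateral group '", g,
                     "' does not share patient_id and year"),
              class = "fp_validation_error")
      }
    }
  }
  invisible(x)
}

new_cohort <- function(x, provenance) {
  structure(x, provenance = provenance,
            class = unique(c("fp_cohort", class(tibble::as_tibble(x)))))
}

empty_provenance <- function(n) {
  tibble::tibble(filter = character(), n_in = integer(),
                 n_out = integer(), n_removed = integer())[0, ] |>
    (\(p) { attr(p, "n0") <- n; p })()
}

record_filter <- function(cohort, name, result) {
  prov <- provenance(cohort)
  n_in <- nrow(cohort)
  n_out <- nrow(result)
  prov <- dplyr::bind_rows(prov, tibble::tibble(
    filter = name, n_in = n_in, n_out = n_out, n_removed = n_in - n_out
  ))
  if (n_out == 0) {
    warn(paste0("filter '", name, "' removed every record"))
  }
  new_cohort(result, provenance = prov)
}

#' Retrieve the filter provenance log of a cohort
#'
#' @param cohort A cohort created by [as_cohort()] or [read_registry()].
#' @return A tibble with columns `filter`, `n_in`, `n_out`, `n_removed`,
#'   one row per filter applied, in application order. Counts reconcile:
#'   `n_in - n_removed == n_out` row-wise and across consecutive stages.
#' @export
provenance <- function(cohort) {
  p <- attr(cohort, "provenance")
  if (is.null(p)) p <- empty_provenance(nrow(cohort))
  p
}

#' Read a surgery registry from delimited text
#'
#' Reads a delimited file (CSV by default, TSV via `delim = "\t"`) with one
#' row per primary surgery, applies an optional column mapping, interprets
#' missing-value tokens, and validates the result into a cohort. Missing BMI
#' or ASA tokens become `NA`, never zeros.
#'
#' @param path Path to the delimited file. A header row is mandatory.
#' @param delim Field delimiter, default `","`.
#' @param na Character vector of tokens parsed as missing; default
#'   `c("", "NA")`.
#' @param col_map Optional named character vector mapping canonical field
#'   names to file column names, e.g. `c(ae90 = "adverse_event_90d")`.
#'   Unmapped canonical names are looked up verbatim.
#' @return A validated cohort (see [as_cohort()]).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write.csv(generate_cohort(synthetic_config(n_surgeons = 4, seed = 1,
#'   years = 2011))$cohort, path, row.names = FALSE, na = "")
#' cohort <- read_registry(path)
#' nrow(cohort)
#' @export
read_registry <- function(path, delim = ",", na = c("", "NA"), col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "fp_io_error")
  }
  raw <- readr::read_delim(
    path, delim = delim, na = na, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        abort(paste0("mapped column '", src, "' (for ", canon,
                     ") not present in file"), class = "fp_config_error")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"bilateral_group" %in% names(raw)) raw$bilateral_group <- NA_character_
  missing_cols <- setdiff(registry_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fp_config_error")
  }
  raw <- raw[registry_columns()]
  for (col in c("year", "age", "bmi", "ae90", "reop2y")) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(parsed))
    if (length(bad) > 0) {
      abort(paste0("unparseable ", col, " value(s) on row(s) ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "fp_validation_error")
    }
    raw[[col]] <- parsed
  }
  as_cohort(raw)
}

#' Collapse same-day bilateral surgeries into single records
#'
#' Patients receiving both hips on the same day contribute a single surgery
#' to the analysis. Each simultaneous pair (two records sharing a
#' `bilateral_group` token) is replaced by its first-listed record, with each
#' binary outcome set to the logical OR of the pair's outcomes: an adverse
#' event or reoperation on either hip counts as an event for the single
#' retained exposure. Staged (different-day) bilaterals carry no group token
#' and are untouched.
#'
#' @param cohort A cohort.
#' @return The cohort with each simultaneous pair collapsed to one record.
#'   The two sides of a pair must name the same surgeon; a pair operated by
#'   two different surgeons is rejected since attribution would be arbitrary.
#' @export
collapse_bilateral <- function(cohort) {
  validate_bilateral_groups(cohort)
  grouped_idx <- which(!is.na(cohort$bilateral_group))
  if (length(grouped_idx) == 0) {
    return(record_filter(cohort, "collapse_bilateral", cohort))
  }
  pairs <- split(grouped_idx, cohort$bilateral_group[grouped_idx])
  drop <- integer(0)
  out <- cohort
  for (idx in pairs) {
    if (length(idx) < 2) next   # singleton group: other side excluded upstream
    idx <- sort(idx)
    if (cohort$surgeon_id[idx[1]] != cohort$surgeon_id[idx[2]]) {
      abort(paste0("bilateral group '", cohort$bilateral_group[idx[1]],
                   "' names two different surgeons"),
            class = "fp_validation_error")
    }
    for (oc in outcome_names()) {
      out[[oc]][idx[1]] <- or_na(cohort[[oc]][idx[1]], cohort[[oc]][idx[2]])
    }
    drop <- c(drop, idx[2])
  }
  result <- if (length(drop) > 0) out[-drop, ] else out
  record_filter(cohort, "collapse_bilateral", result)
}

or_na <- function(a, b) {
  if (is.na(a) && is.na(b)) return(NA_real_)
  max(a, b, na.rm = TRUE)
}

#' Keep only records complete on a set of covariates
#'
#' Complete-case inclusion: records with any missing value among the
#' `required` covariates are removed, and the removal count is logged in the
#' cohort's provenance. An empty result is legal (it is flagged with a
#' warning through the provenance machinery), and `required = character(0)`
#' is the identity.
#'
#' @param cohort A cohort.
#' @param required Character vector of covariate names among
#'   `age, sex, bmi, asa, diagnosis, grade`.
#' @return The filtered cohort.
#' @export
complete_case_filter <- function(cohort, required) {
  bad <- setdiff(required, registry_covariates())
  if (length(bad) > 0) {
    abort(paste0("unknown covariate(s): ", paste(bad, collapse = ", ")),
          class = "fp_config_error")
  }
  keep <- rep(TRUE, nrow(cohort))
  for (col in required) keep <- keep & !is.na(cohort[[col]])
  record_filter(cohort, paste0("complete_case[", paste(required, collapse = ","), "]"),
                cohort[keep, ])
}

#' Split a cohort into analysis strata
#'
#' @param cohort A cohort with `year` populated on every record.
#' @param by_year If `TRUE` (default), partition into one stratum per
#'   calendar year; the strata are disjoint and exhaustive. If `FALSE`,
#'   return a single pooled stratum named `"all_years"`.
#' @return A named list of cohorts (names are years, or `"all_years"`).
#' @export
stratify <- function(cohort, by_year = TRUE) {
  if (anyNA(cohort$year)) {
    abort("year missing on some records; stratification requires year",
          class = "fp_validation_error")
  }
  if (!by_year) {
    out <- list(all_years = record_filter(cohort, "stratify[all_years]", cohort))
    return(out)
  }
  years <- sort(unique(cohort$year))
  out <- lapply(years, function(y) {
    record_filter(cohort, paste0("stratify[", y, "]"),
                  cohort[cohort$year == y, ])
  })
  names(out) <- as.character(years)
  out
}

#' Restrict a stratum to surgeons above a volume threshold
#'
#' Implements the annual-volume sub-analysis: within the stratum, surgeons
#' whose surgery count is `> threshold` (when `strict`, the default, per
#' "more than 10 annually") or `>= threshold` (when `strict = FALSE`, the
#' "10 or more" reading) are retained with all their records.
#'
#' @param cohort A single-stratum cohort (typically one calendar year).
#' @param threshold Non-negative integer volume threshold.
#' @param strict If `TRUE`, keep surgeons with count strictly above the
#'   threshold; if `FALSE`, keep counts equal to the threshold too.
#' @return The filtered cohort.
#' @export
volume_filter <- function(cohort, threshold, strict = TRUE) {
  if (threshold < 0) {
    abort("threshold must be >= 0", class = "fp_config_error")
  }
  counts <- table(cohort$surgeon_id)
  keep_ids <- names(counts)[if (strict) counts > threshold else counts >= threshold]
  record_filter(
    cohort,
    paste0("volume[", if (strict) ">" else ">=", threshold, "]"),
    cohort[cohort$surgeon_id %in% keep_ids, ]
  )
}

#' Write per-surgeon summaries to delimited text
#'
#' One row per surgeon per stratum; reading the file back reproduces integer
#' fields bit-identically and real fields to at least 12 significant digits.
#'
#' @param summaries A non-empty tibble of surgeon summaries
#'   (see [summarize_surgeons()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    abort("summaries must be non-empty", class = "fp_config_error")
  }
  out <- tryCatch(
    readr::write_csv(summaries, path),
    error = function(e) abort(paste0("cannot write ", path, ": ", conditionMessage(e)),
                              class = "fp_io_error")
  )
  invisible(path)
}

#' Read back summaries written by [write_summaries()]
#' @param path File produced by [write_summaries()].
#' @return A tibble.
#' @export
read_summaries <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
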