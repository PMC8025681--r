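#' Define a profiling analysis plan
#'
#' Collects every choice of the full profiling run: which outcomes to
#' analyse, which strata (annual, pooled over all years, or both), an
#' optional annual volume threshold, the predictor set per outcome, and the
#' funnel configuration.
#'
#' @param outcomes Outcomes to analyse, subset of `c("ae90", "reop2y")`.
#' @param strata `"annual"`, `"pooled"`, or both (default).
#' @param volume_threshold Optional integer; when set, annual strata are
#'   restricted to surgeons above this annual volume before modelling
#'   (see [volume_filter()]). The pooled stratum is never volume-filtered:
#'   the threshold is an *annual* volume rule.
#' @param volume_strict Strictly above (`TRUE`, default) vs at-or-above.
#' @param predictors Named list of predictor sets per outcome; defaults to
#'   [risk_predictors()] for each.
#' @param funnel A [funnel_config()].
#' @param outdir Optional directory; when set, [run_analysis()] persists
#'   summaries, counts, flags and figures there.
#' @return A list of class `analysis_plan`.
#' @export
analysis_plan <- function(outcomes = c("ae90", "reop2y"),
                          strata = c("annual", "pooled"),
                          volume_threshold = NULL,
                          volume_strict = TRUE,
                          predictors = NULL,
                          funnel = funnel_config(),
                          outdir = NULL) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  strata <- match.arg(strata, several.ok = TRUE)
  if (is.null(predictors)) {
    predictors <- setNames(lapply(outcomes, risk_predictors), outcomes)
  }
  missing_sets <- setdiff(outcomes, names(predictors))
  if (length(missing_sets) > 0) {
    abort(paste0("no predictor set for: ", paste(missing_sets, collapse = ", ")),
          class = "fp_config_error")
  }
  structure(list(outcomes = outcomes, strata = strata,
                 volume_threshold = volume_threshold,
                 volume_strict = volume_strict,
                 predictors = predictors, funnel = funnel, outdir = outdir),
            class = "analysis_plan")
}

#' Run the full surgeon-profiling analysis
#'
#' Executes, for every outcome and stratum of the plan: complete-case
#' filtering on that outcome's predictors, the optional annual volume
#' filter, a within-stratum logistic risk-model fit, per-surgeon
#' observed/expected summaries, funnel classification, and outlier counting.
#' Simultaneous bilateral pairs are collapsed once, up front. The run is
#' deterministic given the input cohort and plan; a stratum whose outcome
#' becomes degenerate (constant) or empty after filtering is reported as
#' skipped rather than crashing the run.
#'
#' @param cohort A cohort (see [as_cohort()], [read_registry()],
#'   [generate_cohort()]).
#' @param plan An [analysis_plan()].
#' @return An object of class `report_bundle`:
#'   \describe{
#'     \item{counts}{annual outlier counts (see [count_outside()])}
#'     \item{results}{named list of `funnel_result`s, one per outcome x
#'       stratum, names like `"ae90/2013"` or `"reop2y/all_years"`}
#'     \item{summaries}{all per-surgeon summaries, row-bound}
#'     \item{models}{tidied coefficients of every fitted model}
#'     \item{surgeons_at_risk}{distinct surgeons per outcome and year after
#'       complete-case filtering, before any volume filter (the funnel's
#'       denominator population)}
#'     \item{skipped}{strata skipped, with the reason}
#'     \item{manifest}{input/plan hashes and sizes for reproducibility
#'       checks}
#'   }
#' @export
run_analysis <- function(cohort, plan = analysis_plan()) {
  if (nrow(cohort) == 0) {
    abort("cohort is empty", class = "fp_config_error")
  }
  cohort <- collapse_bilateral(cohort)

  results <- list()
  summaries <- list()
  models <- list()
  skipped <- list()
  at_risk <- list()

  for (outcome in plan$outcomes) {
    preds <- plan$predictors[[outcome]]
    cc <- complete_case_filter(cohort, preds)
    at_risk[[outcome]] <- cc |>
      dplyr::distinct(.data$year, .data$surgeon_id) |>
      dplyr::count(.data$year, name = "n_surgeons") |>
      dplyr::mutate(outcome = outcome, .before = 1)

    strata <- list()
    if ("annual" %in% plan$strata) strata <- c(strata, stratify(cc, by_year = TRUE))
    if ("pooled" %in% plan$strata) strata <- c(strata, stratify(cc, by_year = FALSE))

    for (label in names(strata)) {
      stratum <- strata[[label]]
      if (!is.null(plan$volume_threshold) && label != "all_years") {
        stratum <- volume_filter(stratum, plan$volume_threshold,
                                 strict = plan$volume_strict)
      }
      key <- paste0(outcome, "/", label)
      step <- tryCatch({
        if (nrow(stratum) == 0) {
          abort("no records after filtering", class = "fp_degenerate_error")
        }
        model <- fit_risk_model(stratum, outcome, preds)
        summ <- summarize_surgeons(stratum, model, stratum_label = label)
        res <- funnel_classify(summ, plan$funnel)
        list(model = model, summ = summ, res = res)
      }, fp_degenerate_error = function(e) e, fp_separation_error = function(e) e)
      if (inherits(step, "condition")) {
        skipped[[key]] <- tibble::tibble(outcome = outcome, stratum = label,
                                         reason = conditionMessage(step))
        next
      }
      results[[key]] <- step$res
      summaries[[key]] <- step$summ
      models[[key]] <- dplyr::mutate(tidy(step$model), outcome = outcome,
                                     stratum = label, .before = 1)
    }
  }

  annual <- results[!grepl("/all_years$", names(results))]
  counts <- if (length(annual) > 0) count_outside(annual) else
    tibble::tibble(stratum = character(), outcome = character(),
                   kind = character(), n_outside = integer(),
                   n_surgeons = integer())

  bundle <- structure(list(
    counts = counts,
    results = results,
    summaries = dplyr::bind_rows(summaries),
    models = dplyr::bind_rows(models),
    surgeons_at_risk = dplyr::bind_rows(at_risk),
    skipped = dplyr::bind_rows(skipped),
    manifest = list(
      n_records_in = nrow(cohort),
      plan = unclass(plan[setdiff(names(plan), "outdir")]),
      input_hash = rlang::hash(as.data.frame(cohort)),
      plan_hash = rlang::hash(unclass(plan[setdiff(names(plan), "outdir")])),
      package_version = as.character(utils::packageVersion("funnelprof"))
    )
  ), class = "report_bundle")

  if (!is.null(plan$outdir)) persist_bundle(bundle, plan$outdir)
  bundle
}

persist_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(bundle$summaries) > 0) {
    write_summaries(bundle$summaries, file.path(outdir, "surgeon_summaries.csv"))
  }
  readr::write_csv(bundle$counts, file.path(outdir, "outlier_counts.csv"))
  readr::write_csv(bundle$models, file.path(outdir, "model_coefficients.csv"))
  readr::write_csv(bundle$surgeons_at_risk,
                   file.path(outdir, "surgeons_at_risk.csv"))
  for (key in names(bundle$results)) {
    res <- bundle$results[[key]]
    if (grepl("/all_years$", key)) {
      render_funnel(res, path = file.path(
        outdir, paste0("funnel_", sub("/", "_", key), ".png")))
    }
  }
  invisible(outdir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Surgeon profiling report bundle\n")
  cat("  strata analysed:", length(x$results),
      " skipped:", nrow(x$skipped), "\n")
  if (nrow(x$counts) > 0) {
    cat("  annual surgeons outside the upper 95% limit:\n")
    wide <- tidyr::pivot_wider(x$counts,
                               id_cols = c("outcome", "kind"),
                               names_from = "stratum",
                               values_from = "n_outside")
    print(as.data.frame(wide), row.names = FALSE)
  }
  invisible(x)
}

#' Render a funnel figure with a data sidecar
#'
#' Writes the funnel plot of a classified stratum to an image file, plus a
#' delimited sidecar (same path with `_data.csv` appended) containing every
#' dot coordinate and limit-curve point, so downstream checks can assert on
#' plot data rather than pixels.
#'
#' @param result A `funnel_result`.
#' @param path Output image path (format from the extension, e.g. `.png`,
#'   `.pdf`).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_funnel <- function(result, path, width = 7, height = 5) {
  p <- autoplot(result)
  tryCatch(
    suppressMessages(ggplot2::ggsave(path, p, width = width, height = height,
                                     dpi = 150)),
    error = function(e) abort(paste0("cannot write ", path, ": ",
                                     conditionMessage(e)),
                              class = "fp_io_error")
  )
  sidecar <- dplyr::bind_rows(
    result$flags |>
      dplyr::distinct(.data$surgeon_id, .data$n, .data$kind, .data$prop) |>
      dplyr::mutate(element = "dot", level = NA_real_) |>
      dplyr::rename(y = "prop"),
    result$curves |>
      dplyr::mutate(element = "curve", surgeon_id = NA_character_,
                    kind = NA_character_) |>
      dplyr::rename(y = "upper")
  ) |>
    dplyr::select("element", "surgeon_id", "kind", "level", "n", "y")
  readr::write_csv(sidecar, paste0(tools::file_path_sans_ext(path), "_data.csv"))
  invisible(path)
}

#' Write the annual outlier-count table
#'
#' Lays the counts out the way register reports print them: one block per
#' outcome with `Observed` and `Standardized` rows, one column per year, and
#' a surgeons-at-risk header row giving the number of distinct surgeons per
#' year (after complete-case filtering, before any volume restriction).
#'
#' @param counts Output of [count_outside()] (or the `counts` element of a
#'   `report_bundle`).
#' @param surgeons_at_risk Optional tibble with `outcome`, `year`,
#'   `n_surgeons` (the `surgeons_at_risk` element of a bundle).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
render_count_table <- function(counts, path, surgeons_at_risk = NULL) {
  if (nrow(counts) == 0) {
    abort("no annual counts to render", class = "fp_config_error")
  }
  years <- sort(unique(counts$stratum))
  blocks <- list()
  for (oc in unique(counts$outcome)) {
    sub <- counts[counts$outcome == oc, ]
    if (!is.null(surgeons_at_risk)) {
      ar <- surgeons_at_risk[surgeons_at_risk$outcome == oc, ]
      blocks[[paste0(oc, "_at_risk")]] <- tibble::tibble(
        outcome = oc, row = "Surgeons at risk",
        !!!setNames(lapply(years, function(y) {
          v <- ar$n_surgeons[as.character(ar$year) == y]
          if (length(v) == 0) NA_integer_ else as.integer(v)
        }), years))
    }
    for (kd in c("observed", "standardized")) {
      kk <- sub[sub$kind == kd, ]
      blocks[[paste0(oc, "_", kd)]] <- tibble::tibble(
        outcome = oc, row = tools::toTitleCase(kd),
        !!!setNames(lapply(years, function(y) {
          v <- kk$n_outside[kk$stratum == y]
          if (length(v) == 0) NA_integer_ else as.integer(v)
        }), years))
    }
  }
  out <- dplyr::bind_rows(blocks)
  readr::write_csv(out, path)
  invisible(path)
}
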