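small_registry <- function(seed = 101, ...) {
  generate_cohort(synthetic_config(n_surgeons = 40, years = 2011:2012,
                                   seed = seed, ...))
}

test_that("run_analysis equals manual composition of the pipeline stages", {
  reg <- small_registry()
  plan <- analysis_plan(outcomes = "ae90", strata = "annual")
  bundle <- run_analysis(reg$cohort, plan)

  # manual staging on the same input
  cc <- complete_case_filter(collapse_bilateral(reg$cohort),
                             risk_predictors("ae90"))
  manual <- lapply(stratify(cc), function(stratum) {
    model <- fit_risk_model(stratum, "ae90")
    funnel_classify(summarize_surgeons(stratum, model), plan$funnel)
  })
  for (year in names(manual)) {
    key <- paste0("ae90/", year)
    expect_equal(bundle$results[[key]]$flags, manual[[year]]$flags)
    expect_equal(bundle$results[[key]]$p_bar, manual[[year]]$p_bar)
  }
  expect_equal(bundle$counts, count_outside(manual))
})

test_that("identical input and plan give identical bundles", {
  reg <- small_registry()
  plan <- analysis_plan()
  b1 <- run_analysis(reg$cohort, plan)
  b2 <- run_analysis(reg$cohort, plan)
  expect_identical(rlang::hash(b1$summaries), rlang::hash(b2$summaries))
  expect_identical(rlang::hash(b1$counts), rlang::hash(b2$counts))
  expect_identical(b1$manifest$input_hash, b2$manifest$input_hash)
})

test_that("volume-thresholded plans only retain high-volume surgeons annually", {
  reg <- small_registry()
  plan <- analysis_plan(outcomes = "ae90", strata = c("annual", "pooled"),
                        volume_threshold = 10, volume_strict = TRUE)
  bundle <- run_analysis(reg$cohort, plan)
  annual <- bundle$summaries[bundle$summaries$stratum != "all_years", ]
  expect_true(all(annual$n > 10))
  # the pooled stratum is never volume-filtered: every complete-case surgeon
  # appears there, including those the annual threshold dropped
  pooled <- bundle$summaries[bundle$summaries$stratum == "all_years", ]
  cc <- complete_case_filter(collapse_bilateral(reg$cohort),
                             risk_predictors("ae90"))
  expect_setequal(pooled$surgeon_id, unique(cc$surgeon_id))
})

test_that("pooled and annual analyses use the same underlying records", {
  reg <- small_registry()
  bundle <- run_analysis(reg$cohort, analysis_plan(outcomes = "ae90"))
  annual_n <- sum(bundle$summaries$n[bundle$summaries$stratum != "all_years"])
  pooled_n <- sum(bundle$summaries$n[bundle$summaries$stratum == "all_years"])
  expect_equal(annual_n, pooled_n)
  annual_obs <- sum(bundle$summaries$observed[bundle$summaries$stratum != "all_years"])
  pooled_obs <- sum(bundle$summaries$observed[bundle$summaries$stratum == "all_years"])
  expect_equal(annual_obs, pooled_obs)
})

test_that("surgeons at risk are counted after complete-case, before volume filtering", {
  reg <- small_registry()
  plan <- analysis_plan(outcomes = "ae90", volume_threshold = 10)
  bundle <- run_analysis(reg$cohort, plan)
  cc <- complete_case_filter(collapse_bilateral(reg$cohort),
                             risk_predictors("ae90"))
  direct <- cc |>
    dplyr::distinct(year, surgeon_id) |>
    dplyr::count(year, name = "n_surgeons")
  expect_equal(bundle$surgeons_at_risk$n_surgeons, direct$n_surgeons)
})

test_that("degenerate strata are skipped, not crashed", {
  # every outcome zero: constant outcome in each stratum
  recs <- toy_records(40, surgeon_id = rep(sprintf("S%02d", 1:4), 10),
                      year = rep(c(2011L, 2012L), each = 20), ae90 = 0)
  bundle <- run_analysis(as_cohort(recs), analysis_plan(outcomes = "ae90"))
  expect_equal(length(bundle$results), 0)
  expect_equal(nrow(bundle$skipped), 3)  # 2 annual + pooled
  expect_match(bundle$skipped$reason[1], "constant")
})

test_that("run_analysis rejects an empty cohort", {
  expect_error(run_analysis(toy_cohort(1)[0, ], analysis_plan()),
               class = "fp_config_error")
})

test_that("rendered funnel figures carry a faithful data sidecar", {
  reg <- small_registry()
  bundle <- run_analysis(reg$cohort, analysis_plan(outcomes = "ae90",
                                                   strata = "pooled"))
  res <- bundle$results[["ae90/all_years"]]
  path <- tempfile(fileext = ".png")
  render_funnel(res, path)
  expect_true(file.exists(path))
  sidecar <- readr::read_csv(paste0(tools::file_path_sans_ext(path), "_data.csv"),
                             show_col_types = FALSE)
  dots <- sidecar[sidecar$element == "dot", ]
  n_surgeons <- length(unique(res$flags$surgeon_id))
  expect_equal(nrow(dots), 2 * n_surgeons)  # observed + standardized per surgeon
  curves <- sidecar[sidecar$element == "curve", ]
  expect_equal(nrow(curves), nrow(res$curves))
  # regenerating produces identical plot data
  path2 <- tempfile(fileext = ".png")
  render_funnel(res, path2)
  sidecar2 <- readr::read_csv(paste0(tools::file_path_sans_ext(path2), "_data.csv"),
                              show_col_types = FALSE)
  expect_identical(sidecar, sidecar2)
})

test_that("a single-surgeon stratum still renders", {
  summ <- tibble::tibble(surgeon_id = "S01", stratum = "2011", outcome = "ae90",
                         n = 30L, observed = 2, expected = 1.9,
                         observed_prop = 2 / 30,
                         standardized_prop = (2 / 1.9) * (2 / 30),
                         p_bar = 2 / 30)
  res <- funnel_classify(summ)
  path <- tempfile(fileext = ".png")
  expect_no_error(render_funnel(res, path))
})

test_that("the count table renders with at-risk header and round-trips", {
  reg <- small_registry()
  bundle <- run_analysis(reg$cohort, analysis_plan())
  path <- tempfile(fileext = ".csv")
  render_count_table(bundle$counts, path,
                     surgeons_at_risk = bundle$surgeons_at_risk)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  # per outcome: at-risk row + observed + standardized
  expect_equal(nrow(tab), 3 * length(unique(bundle$counts$outcome)))
  expect_setequal(setdiff(names(tab), c("outcome", "row")),
                  sort(unique(bundle$counts$stratum)))
  obs_row <- tab[tab$outcome == "ae90" & tab$row == "Observed", ]
  direct <- bundle$counts[bundle$counts$outcome == "ae90" &
                            bundle$counts$kind == "observed", ]
  expect_equal(unlist(obs_row[as.character(direct$stratum)],
                      use.names = FALSE), direct$n_outside)

  # zero-count input keeps the correct shape
  zero <- bundle$counts
  zero$n_outside <- 0L
  path0 <- tempfile(fileext = ".csv")
  render_count_table(zero, path0)
  tab0 <- readr::read_csv(path0, show_col_types = FALSE)
  expect_true(all(tab0[["2011"]] == 0))
})

test_that("persisted bundles write summaries, counts and figures", {
  reg <- small_registry()
  outdir <- tempfile("bundle")
  run_analysis(reg$cohort, analysis_plan(outcomes = "ae90",
                                         strata = c("annual", "pooled"),
                                         outdir = outdir))
  expect_true(file.exists(file.path(outdir, "surgeon_summaries.csv")))
  expect_true(file.exists(file.path(outdir, "outlier_counts.csv")))
  expect_true(file.exists(file.path(outdir, "model_coefficients.csv")))
  expect_true(file.exists(file.path(outdir, "funnel_ae90_all_years.png")))
})
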