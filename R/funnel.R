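#' Upper Wilson score bound
#'
#' The upper limit of the Wilson score interval for a binomial proportion,
#' the interval obtained by inverting the score test. For centre proportion
#' `p`, denominator `n` and standard-normal quantile `z`:
#' \deqn{u = \frac{p + z^2/2n + z\sqrt{p(1-p)/n + z^2/4n^2}}{1 + z^2/n}.}
#' The Wilson interval behaves well at small `n` and extreme proportions,
#' which is why it is the method of choice for funnel control limits around
#' low-volume providers. Confidence levels are two-sided conventions: the
#' 95% limit uses `z = qnorm(0.975)` and the 99.8% limit `z = qnorm(0.999)`.
#'
#' @param p_center Centre proportion(s) in \[0, 1\] (for funnel limits, the
#'   stratum mean event proportion).
#' @param n Denominator(s), positive integers.
#' @param level Confidence level(s) in (0, 1), default 0.95.
#' @param one_sided If `TRUE`, treat `level` as a one-sided tail probability
#'   (`z = qnorm(level)`) instead of the default two-sided convention.
#' @return Upper bound(s) in \[`p_center`, 1\]. Vectorized over all
#'   arguments.
#' @examples
#' wilson_upper(0, 10, 0.95)          # z^2 / (n + z^2)
#' wilson_upper(0.062, 27, 0.95)
#' @export
wilson_upper <- function(p_center, n, level = 0.95, one_sided = FALSE) {
  check_wilson_args(p_center, n, level)
  z <- if (one_sided) qnorm(level) else qnorm(1 - (1 - level) / 2)
  (p_center + z^2 / (2 * n) +
     z * sqrt(p_center * (1 - p_center) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

#' Lower Wilson score bound
#' @inheritParams wilson_upper
#' @return Lower bound(s) in \[0, `p_center`\].
#' @export
wilson_lower <- function(p_center, n, level = 0.95, one_sided = FALSE) {
  check_wilson_args(p_center, n, level)
  z <- if (one_sided) qnorm(level) else qnorm(1 - (1 - level) / 2)
  (p_center + z^2 / (2 * n) -
     z * sqrt(p_center * (1 - p_center) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

check_wilson_args <- function(p, n, level) {
  if (any(n < 1)) abort("n must be >= 1", class = "fp_domain_error")
  if (any(p < 0 | p > 1)) abort("p_center must lie in [0, 1]",
                                class = "fp_domain_error")
  if (any(level <= 0 | level >= 1)) abort("level must lie in (0, 1)",
                                          class = "fp_domain_error")
  invisible(NULL)
}

# Score-test inversion variant of the upper funnel limit: the smallest
# observed proportion whose lower Wilson bound exceeds p_bar. By the duality
# of the Wilson interval and the score test this is
# p_bar + z * sqrt(p_bar (1 - p_bar) / n), capped at 1; it agrees with the
# Wilson-slot limit to O(1/n).
score_inversion_upper <- function(p_bar, n, level, one_sided = FALSE) {
  check_wilson_args(p_bar, n, level)
  z <- if (one_sided) qnorm(level) else qnorm(1 - (1 - level) / 2)
  pmin(1, p_bar + z * sqrt(p_bar * (1 - p_bar) / n))
}

#' Configure funnel control limits
#'
#' @param levels Confidence levels of the control limits; default
#'   `c(0.95, 0.998)` (the 95% and 99.8% limits of register practice).
#' @param method `"wilson"` (default): the limit at denominator `n` is the
#'   upper Wilson bound with the stratum mean in the observed-proportion
#'   slot. `"inversion"`: the smallest observed proportion whose lower
#'   Wilson bound exceeds the stratum mean (score-test inversion); the two
#'   agree to within `1/n`.
#' @param side `"upper_only"` (default; only the upper limit is used for
#'   flagging) or `"both"`.
#' @param grid Denominators at which limit curves are evaluated for
#'   plotting; strictly increasing positive integers. Default `1:300`.
#' @param one_sided Treat levels as one-sided tail probabilities instead of
#'   the default two-sided convention.
#' @return A list of class `funnel_config`.
#' @export
funnel_config <- function(levels = c(0.95, 0.998),
                          method = c("wilson", "inversion"),
                          side = c("upper_only", "both"),
                          grid = 1:300,
                          one_sided = FALSE) {
  method <- match.arg(method)
  side <- match.arg(side)
  if (any(levels <= 0 | levels >= 1)) {
    abort("levels must lie in (0, 1)", class = "fp_domain_error")
  }
  if (length(grid) == 0 || any(grid < 1) || any(diff(grid) <= 0)) {
    abort("grid must be strictly increasing positive integers",
          class = "fp_domain_error")
  }
  structure(list(levels = sort(levels), method = method, side = side,
                 grid = as.integer(grid), one_sided = one_sided),
            class = "funnel_config")
}

funnel_limit <- function(p_bar, n, level, config) {
  if (config$method == "wilson") {
    wilson_upper(p_bar, n, level, config$one_sided)
  } else {
    score_inversion_upper(p_bar, n, level, config$one_sided)
  }
}

#' Funnel control-limit curves
#'
#' Evaluates the upper (and optionally lower) control limit at every
#' denominator of the plotting grid, for every configured level. Upper
#' curves start wide at small `n` — a small sample size widens the control
#' limit — and decrease monotonically toward the stratum mean as `n` grows.
#'
#' @param p_bar Stratum event proportion the funnel is centred on.
#' @param config A [funnel_config()].
#' @return A tibble with columns `level`, `n`, `upper` (and `lower` when
#'   `side = "both"`).
#' @export
funnel_curves <- function(p_bar, config = funnel_config()) {
  if (length(config$grid) == 0) {
    abort("empty grid", class = "fp_domain_error")
  }
  out <- tidyr::expand_grid(level = config$levels, n = config$grid)
  out$upper <- funnel_limit(p_bar, out$n, out$level, config)
  if (config$side == "both") {
    out$lower <- if (config$method == "wilson") {
      wilson_lower(p_bar, out$n, out$level, config$one_sided)
    } else {
      pmax(0, p_bar - (funnel_limit(p_bar, out$n, out$level, config) - p_bar))
    }
  }
  out
}

#' Classify surgeons against funnel control limits
#'
#' For each surgeon, confidence level, and proportion kind (observed and
#' standardized), the surgeon is outside the funnel exactly when the
#' proportion strictly exceeds the upper control limit at the surgeon's own
#' denominator; a proportion exactly on the limit is inside. Flags nest: a
#' surgeon outside the 99.8% limit is necessarily outside the 95% limit.
#'
#' @param summaries Per-surgeon summaries of one stratum
#'   ([summarize_surgeons()]).
#' @param config A [funnel_config()].
#' @return An object of class `funnel_result`: the stratum label, `p_bar`,
#'   the limit `curves`, and a tidy `flags` tibble (one row per surgeon x
#'   level x kind with the proportion, the limit at the surgeon's `n`, and
#'   the `outside` flag). Supports [ggplot2::autoplot()].
#' @export
funnel_classify <- function(summaries, config = funnel_config()) {
  stratum <- unique(summaries$stratum)
  if (length(stratum) != 1) {
    abort("summaries must come from a single stratum", class = "fp_config_error")
  }
  p_bar <- unique(summaries$p_bar)
  if (length(p_bar) != 1) {
    abort("summaries carry inconsistent p_bar", class = "fp_config_error")
  }
  flags <- tidyr::expand_grid(
    dplyr::select(summaries, "surgeon_id", "n", "observed_prop",
                  "standardized_prop"),
    level = config$levels
  ) |>
    tidyr::pivot_longer(cols = c("observed_prop", "standardized_prop"),
                        names_to = "kind", values_to = "prop") |>
    dplyr::mutate(
      kind = sub("_prop$", "", .data$kind),
      limit = funnel_limit(p_bar, .data$n, .data$level, config),
      outside = .data$prop > .data$limit
    ) |>
    dplyr::select("surgeon_id", "n", "level", "kind", "prop", "limit",
                  "outside")
  structure(list(
    stratum = stratum,
    outcome = unique(summaries$outcome),
    p_bar = p_bar,
    config = config,
    curves = funnel_curves(p_bar, config),
    flags = flags,
    summaries = summaries
  ), class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("Funnel classification (", x$outcome, ", stratum ", x$stratum, ")\n",
      sep = "")
  cat("  p_bar =", signif(x$p_bar, 4), " surgeons =",
      length(unique(x$flags$surgeon_id)), "\n")
  out <- x$flags |>
    dplyr::filter(.data$outside) |>
    dplyr::count(.data$level, .data$kind)
  if (nrow(out) == 0) cat("  no surgeon outside any limit\n")
  else print(as.data.frame(out), row.names = FALSE)
  invisible(x)
}

#' Count surgeons outside the upper 95% control limit per year
#'
#' Reproduces the annual outlier-count table layout: one row per outcome x
#' proportion kind (observed, standardized), one column per year, counting
#' the surgeons strictly above the upper limit at the chosen level.
#'
#' @param results A list of `funnel_result` objects, one per annual stratum.
#' @param level The flagging level, default 0.95.
#' @return A tibble with columns `stratum`, `outcome`, `kind`, `n_outside`,
#'   `n_surgeons`.
#' @export
count_outside <- function(results, level = 0.95) {
  if (inherits(results, "funnel_result")) results <- list(results)
  purrr::map_dfr(results, function(res) {
    res$flags |>
      dplyr::filter(abs(.data$level - !!level) < 1e-9) |>
      dplyr::group_by(.data$kind) |>
      dplyr::summarise(n_outside = sum(.data$outside),
                       n_surgeons = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(stratum = res$stratum, outcome = res$outcome) |>
      dplyr::select("stratum", "outcome", "kind", "n_outside", "n_surgeons")
  })
}

#' Funnel plot of surgeon outcomes
#'
#' Renders the standard register-style funnel: per-surgeon proportions
#' against volume, a horizontal green line at the stratum mean, a yellow
#' 95% and red 99.8% upper control-limit curve, red dots for observed and
#' blue dots for standardized proportions. Standardized proportions above
#' the axis ceiling are clipped for display only.
#'
#' @param object A `funnel_result` from [funnel_classify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.funnel_result <- function(object, ...) {
  dots <- object$flags |>
    dplyr::distinct(.data$surgeon_id, .data$n, .data$kind, .data$prop)
  curves <- object$curves |>
    dplyr::mutate(level_lab = paste0(100 * .data$level, "% limit"))
  level_cols <- setNames(c("#E6B800", "#CC0000"),
                         paste0(100 * sort(object$config$levels), "% limit"))
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$n, y = .data$upper, colour = .data$level_lab)) +
    ggplot2::geom_hline(yintercept = object$p_bar, colour = "darkgreen") +
    ggplot2::geom_point(
      data = dots,
      ggplot2::aes(x = .data$n, y = pmin(.data$prop, 1), shape = .data$kind,
                   fill = .data$kind),
      colour = "black", size = 1.8, stroke = 0.2) +
    ggplot2::scale_shape_manual(values = c(observed = 21, standardized = 21)) +
    ggplot2::scale_fill_manual(values = c(observed = "#CC0000",
                                          standardized = "#3366CC")) +
    ggplot2::scale_colour_manual(values = level_cols) +
    ggplot2::labs(
      x = "Surgeries per surgeon", y = "Event proportion",
      colour = NULL, fill = NULL, shape = NULL,
      title = paste0("Funnel plot: ", object$outcome,
                     " (stratum ", object$stratum, ")"),
      subtitle = paste0("mean proportion ", signif(object$p_bar, 3))
    ) +
    ggplot2::coord_cartesian(ylim = c(0, min(1, max(c(
      dots$prop, object$curves$upper)) * 1.05))) +
    ggplot2::theme_minimal()
}
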