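#' Default predictor sets per outcome
#'
#' For adverse events within 90 days all five patient risk factors are used:
#' age, sex, ASA classification, BMI, and diagnosis for implantation. For
#' reoperation within 2 years the model uses sex, ASA classification and
#' BMI.
#'
#' @param outcome `"ae90"` or `"reop2y"`.
#' @return Character vector of covariate names.
#' @export
risk_predictors <- function(outcome = c("ae90", "reop2y")) {
  outcome <- match.arg(outcome)
  switch(outcome,
         ae90 = c("age", "sex", "asa", "bmi", "diagnosis"),
         reop2y = c("sex", "asa", "bmi"))
}

# Encoded design columns for a predictor set. Age and BMI enter linearly;
# sex is a male indicator (reference female, the majority class); ASA is
# categorical with reference I and grades III and IV merged (IV is too rare
# to estimate separately without separation risk); diagnosis is a
# secondary-OA indicator (reference primary OA).
encode_predictors <- function(data, predictors) {
  cols <- list()
  for (p in predictors) {
    if (p == "age") cols$age <- as.numeric(data$age)
    else if (p == "bmi") cols$bmi <- as.numeric(data$bmi)
    else if (p == "sex") {
      check_levels(data$sex, c("female", "male"), "sex")
      cols$sex_male <- as.numeric(data$sex == "male")
    } else if (p == "asa") {
      check_levels(data$asa, c("I", "II", "III", "IV"), "asa")
      cols$asa_II <- as.numeric(data$asa == "II")
      cols$asa_III_IV <- as.numeric(data$asa %in% c("III", "IV"))
    } else if (p == "diagnosis") {
      check_levels(data$diagnosis, c("primary_OA", "secondary_OA"), "diagnosis")
      cols$diagnosis_secondary <- as.numeric(data$diagnosis == "secondary_OA")
    } else if (p == "grade") {
      check_levels(data$grade, c("specialist", "trainee"), "grade")
      cols$grade_trainee <- as.numeric(data$grade == "trainee")
    } else {
      abort(paste0("unknown predictor: ", p), class = "fp_config_error")
    }
  }
  tibble::new_tibble(cols, nrow = nrow(data))
}

check_levels <- function(v, levels, what) {
  obs <- unique(as.character(v[!is.na(v)]))
  unseen <- setdiff(obs, levels)
  if (length(unseen) > 0) {
    abort(paste0("unseen ", what, " level(s): ", paste(unseen, collapse = ", ")),
          class = "fp_encoding_error")
  }
  invisible(v)
}

#' Fit a logistic risk model for a binary surgical outcome
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of the outcome on the encoded patient risk
#' factors. The cohort must be complete-case with respect to the predictors;
#' non-convergence and (quasi-)separation are reported as errors rather than
#' returned silently. With `firth = TRUE` a Jeffreys-prior penalized fit
#' (Firth correction) is used instead, which keeps estimates finite in
#' separation-prone small strata.
#'
#' @param cohort A cohort, complete on `predictors`.
#' @param outcome `"ae90"` or `"reop2y"`.
#' @param predictors Covariate names; defaults to [risk_predictors()] for
#'   the outcome. `character(0)` fits an intercept-only model, under which
#'   standardization reduces to the identity on observed proportions.
#' @param firth Use Firth's penalized likelihood instead of plain ML.
#' @return An object of class `risk_model`: the encoding description,
#'   coefficient vector `beta` (intercept first, logit scale), standard
#'   errors, `n_fit`, `converged`, and the maximized log-likelihood.
#'   Supports [predict_prob()], [tidy()] and [glance()].
#' @export
fit_risk_model <- function(cohort, outcome = c("ae90", "reop2y"),
                           predictors = risk_predictors(outcome),
                           firth = FALSE) {
  outcome <- match.arg(outcome)
  y <- cohort[[outcome]]
  if (anyNA(y)) {
    abort(paste0(outcome, " missing on some records"), class = "fp_validation_error")
  }
  enc <- encode_predictors(cohort, predictors)
  if (anyNA(enc)) {
    abort("predictors contain missing values; apply complete_case_filter() first",
          class = "fp_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort(paste0("outcome ", outcome, " is constant; degenerate fit"),
          class = "fp_degenerate_error")
  }
  if (nrow(enc) <= ncol(enc) + 1) {
    abort("fewer records than parameters", class = "fp_degenerate_error")
  }

  if (firth) {
    fit <- firth_logistic(cbind(`(Intercept)` = 1, as.matrix(enc)), y)
    beta <- fit$beta
    se <- fit$se
    converged <- fit$converged
    ll <- fit$loglik
    fitted_p <- fit$fitted
  } else {
    df <- dplyr::bind_cols(tibble::tibble(.y = y), enc)
    fit <- suppressWarnings(
      glm(.y ~ ., data = df, family = binomial(), control = list(
        epsilon = 1e-10, maxit = 100))
    )
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    converged <- fit$converged
    ll <- as.numeric(logLik(fit))
    fitted_p <- fit$fitted.values
    detect_separation(beta, fitted_p)
    if (!converged) {
      abort("logistic fit did not converge", class = "fp_convergence_error")
    }
  }

  structure(list(
    outcome = outcome,
    predictors = predictors,
    terms = names(beta),
    beta = beta,
    se = se,
    n_fit = nrow(enc),
    converged = converged,
    loglik = ll,
    firth = firth,
    fitted = fitted_p
  ), class = "risk_model")
}

# Flags (quasi-)separation: a divergent coefficient together with fitted
# probabilities pinned at 0/1.
detect_separation <- function(beta, fitted_p) {
  eps <- 1e-8
  huge <- which(abs(beta[-1]) > 15)
  if (length(huge) > 0 && (any(fitted_p < eps) || any(fitted_p > 1 - eps))) {
    abort(paste0("complete or quasi-complete separation on: ",
                 paste(names(beta[-1])[huge], collapse = ", ")),
          class = "fp_separation_error")
  }
  invisible(NULL)
}

# Firth's bias-reduced logistic regression: Newton iterations on the
# Jeffreys-penalized score U(b) + 0.5 * X' (h * (1 - 2p)), h the hat
# diagonal of the weighted design.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XW <- X * sqrt(W)
    XtWX <- crossprod(XW)
    XtWX_inv <- solve(XtWX)
    h <- rowSums((XW %*% XtWX_inv) * XW)
    score <- drop(crossprod(X, (y - p) + h * (0.5 - p)))
    step <- drop(XtWX_inv %*% score)
    # step-halving to keep the penalized likelihood moving uphill
    for (half in 0:10) {
      beta_new <- beta + step / 2^half
      p_new <- plogis(drop(X %*% beta_new))
      ll_new <- sum(y * log(p_new) + (1 - y) * log(1 - p_new)) +
        0.5 * determinant_logdet(X, p_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  p <- plogis(drop(X %*% beta))
  W <- p * (1 - p)
  info <- crossprod(X * sqrt(W))
  list(beta = setNames(beta, colnames(X)),
       se = sqrt(diag(solve(info))),
       converged = converged,
       loglik = sum(y * log(p) + (1 - y) * log(1 - p)),
       fitted = p)
}

determinant_logdet <- function(X, p) {
  W <- p * (1 - p)
  as.numeric(determinant(crossprod(X * sqrt(W)), logarithm = TRUE)$modulus)
}

#' Predict event probabilities for surgery records
#'
#' Evaluates `plogis(b0 + x'beta)` under a fitted risk model. Records must
#' be complete on the model's predictors; a categorical level unseen by the
#' encoding is an error (there is no silent reference-level fallback).
#'
#' @param model A `risk_model` from [fit_risk_model()].
#' @param newdata A cohort or data frame of surgery records.
#' @return Numeric vector of event probabilities in (0, 1).
#' @export
predict_prob <- function(model, newdata) {
  enc <- encode_predictors(newdata, model$predictors)
  if (anyNA(enc)) {
    abort("records with missing predictor values cannot be scored",
          class = "fp_validation_error")
  }
  X <- cbind(1, as.matrix(enc))
  expected_terms <- model$terms
  got <- c("(Intercept)", colnames(enc))
  if (!identical(got, expected_terms)) {
    abort(paste0("encoded terms do not match the model: expected ",
                 paste(expected_terms, collapse = ", ")),
          class = "fp_encoding_error")
  }
  plogis(drop(X %*% model$beta))
}

#' Indirectly standardized event proportion
#'
#' The standardized proportion of a surgeon is the ratio of observed to
#' expected events multiplied by the overall event proportion of the
#' stratum: `(O / E) * p_bar`. It exceeds `p_bar` exactly when the surgeon
#' observed more events than their case mix predicts, and may exceed 1 for
#' extreme ratios (it is clipped only for plotting, never for analysis).
#'
#' @param observed Observed event count(s), `O >= 0`.
#' @param expected Expected event count(s) from the risk model, `E > 0`.
#' @param p_bar Overall event proportion of the stratum, in \[0, 1\].
#' @return `(observed / expected) * p_bar`, vectorized.
#' @examples
#' standardized_proportion(3, 1.5, 0.062)  # 0.124
#' @export
standardized_proportion <- function(observed, expected, p_bar) {
  if (any(expected <= 0)) {
    abort("expected events must be > 0", class = "fp_domain_error")
  }
  if (any(observed < 0) || any(p_bar < 0 | p_bar > 1)) {
    abort("observed must be >= 0 and p_bar in [0, 1]", class = "fp_domain_error")
  }
  (observed / expected) * p_bar
}

#' Per-surgeon observed and standardized summaries
#'
#' Tallies, for each surgeon in the stratum, the number of surgeries `n`,
#' observed events `O`, expected events `E` (the sum of model-predicted
#' probabilities over the surgeon's patients), the observed proportion
#' `O/n`, and the indirectly standardized proportion `(O/E) * p_bar`, where
#' `p_bar` is the stratum-wide event proportion. The model is expected to be
#' fitted on this same stratum, so that the logistic score equations make
#' total expected equal total observed.
#'
#' @param cohort A single-stratum cohort, complete on the model predictors.
#' @param model A `risk_model` fitted on this cohort.
#' @param stratum_label Label stored in the `stratum` column (a year, or
#'   `"all_years"`). Defaults to the cohort's single year if unique.
#' @return A tibble with one row per surgeon: `surgeon_id`, `stratum`,
#'   `outcome`, `n`, `observed`, `expected`, `observed_prop`,
#'   `standardized_prop`, `p_bar`.
#' @export
summarize_surgeons <- function(cohort, model, stratum_label = NULL) {
  if (is.null(stratum_label)) {
    yrs <- unique(cohort$year)
    stratum_label <- if (length(yrs) == 1) as.character(yrs) else "all_years"
  }
  probs <- predict_prob(model, cohort)
  y <- cohort[[model$outcome]]
  p_bar <- mean(y)
  out <- tibble::tibble(surgeon_id = cohort$surgeon_id,
                        .y = y, .p = probs) |>
    dplyr::group_by(.data$surgeon_id) |>
    dplyr::summarise(n = dplyr::n(),
                     observed = sum(.data$.y),
                     expected = sum(.data$.p),
                     .groups = "drop") |>
    dplyr::mutate(
      stratum = stratum_label,
      outcome = model$outcome,
      observed_prop = .data$observed / .data$n,
      standardized_prop = standardized_proportion(.data$observed,
                                                  .data$expected, p_bar),
      p_bar = p_bar
    ) |>
    dplyr::select("surgeon_id", "stratum", "outcome", "n", "observed",
                  "expected", "observed_prop", "standardized_prop", "p_bar")
  stopifnot(all(out$expected > 0 | out$n == 0))
  out
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Logistic risk model for", x$outcome,
      if (x$firth) "(Firth penalized)" else "(ML)", "\n")
  cat("  n =", x$n_fit, " logLik =", signif(x$loglik, 6),
      " converged:", x$converged, "\n")
  print(signif(x$beta, 4))
  invisible(x)
}

#' Tidy a fitted risk model
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`
#'   (logit scale), `std.error`, `statistic`, `p.value`, and the
#'   corresponding odds ratio.
#' @exportS3Method generics::tidy
tidy.risk_model <- function(x, ...) {
  z <- x$beta / x$se
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    odds.ratio = unname(exp(x$beta))
  )
}

#' One-row model summary
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble with `outcome`, `n`, `df`, `logLik`, `converged`,
#'   `firth`.
#' @exportS3Method generics::glance
glance.risk_model <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n_fit,
                 df = length(x$beta), logLik = x$loglik,
                 converged = x$converged, firth = x$firth)
}
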