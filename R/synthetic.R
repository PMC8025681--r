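#' Configure the synthetic registry generator
#'
#' Builds the full parameterization of a synthetic hip-arthroplasty cohort:
#' covariate marginals, the surgeon volume distribution, true logit-scale
#' outcome coefficients, target marginal event rates, missingness, and the
#' RNG seed. The defaults emulate a six-year regional register of primary
#' total hip arthroplasties: 208 surgeons with mean annual volume 27 (SD 17),
#' 59% female patients, mean age 69, mean BMI 28, ASA distribution of
#' roughly 25/60/14.5/0.5% over grades I-IV, 5% secondary osteoarthritis,
#' 9% of surgeries by trainees, and marginal event rates of 6.2% for adverse
#' events within 90 days and 1.8% for reoperation within 2 years.
#'
#' True coefficients are on the logit scale, named by encoded predictor
#' column. The intercept is never configured: it is calibrated by
#' [calibrate_intercept()] so that the generated marginal rate hits the
#' target. By default the ASA III and IV coefficients are equal, so the
#' analysis encoding that merges III and IV is correctly specified.
#'
#' @param n_surgeons Number of surgeons.
#' @param years Integer vector of calendar years covered.
#' @param volume_mean,volume_sd Mean and SD of annual surgeon volume
#'   (surgeries/surgeon/year). Draws come from a moment-matched lognormal,
#'   rounded and zero-truncated: registry volumes are right-skewed, with a
#'   non-trivial low-volume tail.
#' @param age_mean,age_sd Age distribution (years), truncated to [17, 100].
#' @param female_prop Proportion of female patients.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m2), truncated to [15, 72].
#' @param asa_probs Probability vector over ASA grades I-IV (sums to 1).
#' @param secondary_oa_prop Proportion with secondary osteoarthritis.
#' @param trainee_prop Proportion of surgeries performed by trainees.
#' @param miss_bmi,miss_asa Missing-completely-at-random proportions applied
#'   to BMI and ASA after outcome generation (the truth uses complete values).
#' @param true_coefs_ae90,true_coefs_reop2y Named logit-scale coefficient
#'   vectors over `age, sex_male, bmi, asa_II, asa_III, asa_IV,
#'   diagnosis_secondary`.
#' @param target_rate_ae90,target_rate_reop2y Target marginal event
#'   proportions.
#' @param surgeon_effect_sd SD of a per-surgeon additive logit-scale effect;
#'   0 (the default) generates in-control surgeons sharing one conditional
#'   event model — the null under which funnel false-flag rates are
#'   calibrated.
#' @param bilateral_prop Proportion of records that are emitted as one side
#'   of a same-day simultaneous bilateral pair (the pair shares patient,
#'   surgeon, year, and a `bilateral_group` token).
#' @param case_mix_confounding If `TRUE`, each surgeon receives a latent
#'   severity score that shifts their patients' ASA distribution
#'   (proportional-odds shift), BMI (+2 kg/m2 per unit) and age (+4 years
#'   per unit), so case mix differs systematically between surgeons while
#'   the conditional outcome model stays common; used to demonstrate that
#'   standardization removes case-mix-driven flags.
#' @param case_mix_strength SD of the per-surgeon case-mix severity score.
#'   The default 1.5 makes the between-surgeon spread of true case-mix event
#'   risk roughly 0.4 on the logit scale — comparable to the spread between
#'   referral and routine practices — which is large enough to be visible
#'   against binomial noise at annual volumes near 27.
#' @param n_hospitals Hospitals that surgeons are assigned to (round-robin).
#' @param seed Integer RNG seed; together with the config it fully
#'   determines the generated cohort.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_surgeons = 208,
                             years = 2011:2016,
                             volume_mean = 27,
                             volume_sd = 17,
                             age_mean = 69,
                             age_sd = 11,
                             female_prop = 0.59,
                             bmi_mean = 28,
                             bmi_sd = 5,
                             asa_probs = c(I = 0.25, II = 0.60, III = 0.145, IV = 0.005),
                             secondary_oa_prop = 0.05,
                             trainee_prop = 0.09,
                             miss_bmi = 0.06,
                             miss_asa = 0.025,
                             true_coefs_ae90 = c(age = 0.02, sex_male = 0.15,
                                                 bmi = 0.04, asa_II = 0.35,
                                                 asa_III = 0.9, asa_IV = 0.9,
                                                 diagnosis_secondary = 0.25),
                             true_coefs_reop2y = c(age = 0, sex_male = 0.25,
                                                   bmi = 0.03, asa_II = 0.3,
                                                   asa_III = 0.8, asa_IV = 0.8,
                                                   diagnosis_secondary = 0),
                             target_rate_ae90 = 0.062,
                             target_rate_reop2y = 0.018,
                             surgeon_effect_sd = 0,
                             bilateral_prop = 0.0045,
                             case_mix_confounding = FALSE,
                             case_mix_strength = 1.5,
                             n_hospitals = 9,
                             seed = 1L) {
  config <- list(
    n_surgeons = as.integer(n_surgeons), years = as.integer(years),
    volume_mean = volume_mean, volume_sd = volume_sd,
    age_mean = age_mean, age_sd = age_sd, female_prop = female_prop,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, asa_probs = asa_probs,
    secondary_oa_prop = secondary_oa_prop, trainee_prop = trainee_prop,
    miss_bmi = miss_bmi, miss_asa = miss_asa,
    true_coefs_ae90 = true_coefs_ae90, true_coefs_reop2y = true_coefs_reop2y,
    target_rate_ae90 = target_rate_ae90, target_rate_reop2y = target_rate_reop2y,
    surgeon_effect_sd = surgeon_effect_sd, bilateral_prop = bilateral_prop,
    case_mix_confounding = isTRUE(case_mix_confounding),
    case_mix_strength = case_mix_strength,
    n_hospitals = as.integer(n_hospitals), seed = as.integer(seed)
  )
  class(config) <- "synthetic_config"
  validate_synthetic_config(config)
  config
}

validate_synthetic_config <- function(config) {
  props <- c(config$female_prop, config$secondary_oa_prop, config$trainee_prop,
             config$miss_bmi, config$miss_asa, config$bilateral_prop,
             config$target_rate_ae90, config$target_rate_reop2y)
  if (any(props < 0 | props > 1)) {
    abort("all proportions must lie in [0, 1]", class = "fp_config_error")
  }
  if (abs(sum(config$asa_probs) - 1) > 1e-12) {
    abort("asa_probs must sum to 1", class = "fp_config_error")
  }
  if (length(config$asa_probs) != 4 || any(config$asa_probs < 0)) {
    abort("asa_probs must be 4 non-negative probabilities over I-IV",
          class = "fp_config_error")
  }
  if (config$volume_mean <= 0) {
    abort("volume_mean must be > 0", class = "fp_config_error")
  }
  if (config$volume_sd < 0 || config$surgeon_effect_sd < 0) {
    abort("volume_sd and surgeon_effect_sd must be >= 0",
          class = "fp_config_error")
  }
  if (config$n_surgeons < 1 || length(config$years) < 1) {
    abort("need at least one surgeon and one year", class = "fp_config_error")
  }
  coef_names <- c("age", "sex_male", "bmi", "asa_II", "asa_III", "asa_IV",
                  "diagnosis_secondary")
  for (nm in c("true_coefs_ae90", "true_coefs_reop2y")) {
    cf <- config[[nm]]
    if (!all(coef_names %in% names(cf)) || anyNA(cf)) {
      abort(paste0(nm, " must be a complete, finite vector named by ",
                   paste(coef_names, collapse = ", ")),
            class = "fp_config_error")
    }
  }
  for (tr in c("target_rate_ae90", "target_rate_reop2y")) {
    if (config[[tr]] <= 0 || config[[tr]] >= 1) {
      abort(paste0(tr, " must lie in (0, 1)"), class = "fp_config_error")
    }
  }
  invisible(config)
}

#' Draw annual surgeon volumes
#'
#' Volumes are drawn per surgeon-year from a lognormal distribution
#' moment-matched to `volume_mean` and `volume_sd`, rounded to integers and
#' truncated below at 1. `volume_sd = 0` degenerates to every volume equal
#' to `round(volume_mean)`. Uses the current RNG state; seed upstream (or
#' use [generate_cohort()], which seeds from the config).
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `surgeon_id`, `year`, `volume`.
#' @export
draw_volumes <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_surgeons * length(config$years)
  ids <- sprintf("S%03d", seq_len(config$n_surgeons))
  grid <- tidyr::expand_grid(surgeon_id = ids, year = config$years)
  if (config$volume_sd == 0) {
    grid$volume <- as.integer(round(config$volume_mean))
  } else {
    cv2 <- (config$volume_sd / config$volume_mean)^2
    sigma2 <- log(1 + cv2)
    mu <- log(config$volume_mean) - sigma2 / 2
    grid$volume <- pmax(1L, as.integer(round(rlnorm(n, mu, sqrt(sigma2)))))
  }
  grid
}

#' Draw patient covariates
#'
#' Age and BMI come from truncated normal distributions (age on [17, 100],
#' BMI on [15, 72], drawn by quantile inversion); sex, ASA grade, diagnosis
#' and surgeon grade are categorical with the configured probabilities.
#' Missingness is *not* applied here — [generate_cohort()] applies it after
#' outcomes are generated, so the data-generating truth always uses the
#' complete value. Uses the current RNG state.
#'
#' @param n Number of patients to draw.
#' @param config A [synthetic_config()].
#' @param asa_shift Optional per-record logit-scale shift of the cumulative
#'   ASA distribution (positive = sicker); used by the case-mix confounding
#'   mechanism.
#' @param bmi_shift Optional per-record shift of the BMI mean (kg/m2).
#' @param age_shift Optional per-record shift of the age mean (years).
#' @return A tibble with columns `age`, `sex`, `bmi`, `asa`, `diagnosis`,
#'   `grade`.
#' @export
draw_covariates <- function(n, config, asa_shift = 0, bmi_shift = 0,
                            age_shift = 0) {
  stopifnot(n > 0)
  tibble::tibble(
    age = rtruncnorm(n, config$age_mean + age_shift, config$age_sd, 17, 100),
    sex = factor(ifelse(runif(n) < config$female_prop, "female", "male"),
                 levels = c("female", "male")),
    bmi = rtruncnorm(n, config$bmi_mean + bmi_shift, config$bmi_sd, 15, 72),
    asa = draw_asa(n, config$asa_probs, asa_shift),
    diagnosis = factor(ifelse(runif(n) < config$secondary_oa_prop,
                              "secondary_OA", "primary_OA"),
                       levels = c("primary_OA", "secondary_OA")),
    grade = factor(ifelse(runif(n) < config$trainee_prop,
                          "trainee", "specialist"),
                   levels = c("specialist", "trainee"))
  )
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

# Proportional-odds shift of the ASA distribution: positive shift moves mass
# toward higher grades.
draw_asa <- function(n, probs, shift = 0) {
  cum <- qlogis(pmin(pmax(cumsum(probs)[1:3], 1e-12), 1 - 1e-12))
  if (length(shift) == 1) shift <- rep(shift, n)
  u <- runif(n)
  grade_idx <- 1L + (u > plogis(cum[1] - shift)) +
    (u > plogis(cum[2] - shift)) + (u > plogis(cum[3] - shift))
  factor(c("I", "II", "III", "IV")[grade_idx], levels = c("I", "II", "III", "IV"))
}

# Linear predictor (without intercept) under the generator's truth encoding.
truth_linear_predictor <- function(covariates, coefs) {
  coefs[["age"]] * covariates$age +
    coefs[["sex_male"]] * (covariates$sex == "male") +
    coefs[["bmi"]] * covariates$bmi +
    coefs[["asa_II"]] * (covariates$asa == "II") +
    coefs[["asa_III"]] * (covariates$asa == "III") +
    coefs[["asa_IV"]] * (covariates$asa == "IV") +
    coefs[["diagnosis_secondary"]] * (covariates$diagnosis == "secondary_OA")
}

#' Calibrate a logistic intercept to a target marginal rate
#'
#' Finds the intercept `b0` such that the sample mean of
#' `plogis(b0 + eta)` equals `target_rate`, where `eta` is the linear
#' predictor of each record under the supplied coefficients. The mean
#' probability is strictly increasing in `b0`, so a monotone root-finder
#' converges; the result is accurate to within 1e-8 in the achieved rate.
#'
#' @param coefs Named coefficient vector (see [synthetic_config()]), or a
#'   pre-computed numeric linear predictor when `covariates` is `NULL`.
#' @param covariates A covariate tibble from [draw_covariates()], or `NULL`
#'   if `coefs` is already the linear predictor.
#' @param target_rate Target marginal event proportion, in (0, 1).
#' @return The intercept on the logit scale.
#' @examples
#' # with all coefficients zero the intercept is the logit of the target
#' calibrate_intercept(rep(0, 10), NULL, 0.062)
#' qlogis(0.062)
#' @export
calibrate_intercept <- function(coefs, covariates, target_rate) {
  if (target_rate <= 0 || target_rate >= 1) {
    abort("target_rate must lie in (0, 1)", class = "fp_config_error")
  }
  eta <- if (is.null(covariates)) as.numeric(coefs)
         else truth_linear_predictor(covariates, coefs)
  if (length(eta) == 0 || anyNA(eta) || any(!is.finite(eta))) {
    abort("linear predictor must be non-empty and finite",
          class = "fp_numeric_error")
  }
  f <- function(b0) mean(plogis(b0 + eta)) - target_rate
  sol <- uniroot(f, lower = qlogis(target_rate) - max(abs(eta)) - 1,
                 upper = qlogis(target_rate) + max(abs(eta)) + 1,
                 tol = 1e-12, maxiter = 200)
  if (abs(f(sol$root)) > 1e-8) {
    abort("intercept calibration did not converge", class = "fp_numeric_error")
  }
  sol$root
}

#' Generate a synthetic registry cohort with known ground truth
#'
#' Draws annual surgeon volumes, patient covariates, and binary outcomes
#' from a logistic mechanism
#' `Bernoulli(plogis(b0 + x'beta + u_surgeon))` with
#' `u ~ Normal(0, surgeon_effect_sd^2)` and the intercept `b0` calibrated so
#' the marginal event rate matches the configured target. A configurable
#' fraction of records is emitted as same-day simultaneous bilateral pairs,
#' and missingness is applied (MCAR) to BMI and ASA after outcome
#' generation. The seed in the config fully determines the output.
#'
#' @param config A [synthetic_config()].
#' @param injected_effects Optional named numeric vector of extra logit-scale
#'   shifts for specific surgeons (names are surgeon IDs such as `"S001"`),
#'   e.g. to plant a known poor performer for power studies.
#' @return A list of class `synthetic_registry` with elements
#'   \describe{
#'     \item{cohort}{a validated cohort (see [as_cohort()])}
#'     \item{truth}{ground truth: calibrated intercepts, true coefficients,
#'       per-surgeon logit effects (random + injected + case-mix severity),
#'       and per-record true event probabilities}
#'     \item{config}{the generating config}
#'   }
#' @export
generate_cohort <- function(config, injected_effects = NULL) {
  validate_synthetic_config(config)
  set.seed(config$seed)

  vols <- draw_volumes(config)
  ids <- unique(vols$surgeon_id)
  hospital_of <- setNames(
    sprintf("H%02d", 1L + (seq_along(ids) - 1L) %% config$n_hospitals), ids)

  u <- setNames(rnorm(length(ids), 0, config$surgeon_effect_sd), ids)
  if (!is.null(injected_effects)) {
    unknown <- setdiff(names(injected_effects), ids)
    if (length(unknown) > 0) {
      abort(paste0("injected_effects name unknown surgeon(s): ",
                   paste(unknown, collapse = ", ")),
            class = "fp_config_error")
    }
    u[names(injected_effects)] <- u[names(injected_effects)] + injected_effects
  }
  severity <- setNames(rep(0, length(ids)), ids)
  if (config$case_mix_confounding) {
    severity <- setNames(rnorm(length(ids), 0, config$case_mix_strength), ids)
  }

  base <- vols[rep(seq_len(nrow(vols)), vols$volume), c("surgeon_id", "year")]
  n <- nrow(base)
  covars <- draw_covariates(
    n, config,
    asa_shift = severity[base$surgeon_id],
    bmi_shift = 2 * severity[base$surgeon_id],
    age_shift = 4 * severity[base$surgeon_id]
  )

  records <- dplyr::bind_cols(
    tibble::tibble(
      record_id = sprintf("R%06d", seq_len(n)),
      patient_id = sprintf("P%06d", seq_len(n)),
      surgeon_id = base$surgeon_id,
      hospital_id = unname(hospital_of[base$surgeon_id]),
      year = base$year
    ),
    covars,
    tibble::tibble(bilateral_group = NA_character_)
  )

  # simultaneous bilateral pairs: duplicate selected records as the second
  # side (same patient, surgeon, day; outcomes drawn independently below)
  n_pairs <- round(config$bilateral_prop * n)
  if (n_pairs > 0) {
    first_side <- sample(n, n_pairs)
    pair_tokens <- sprintf("B%05d", seq_len(n_pairs))
    records$bilateral_group[first_side] <- pair_tokens
    second <- records[first_side, ]
    second$record_id <- sprintf("R%06dB", first_side)
    records <- dplyr::bind_rows(records, second)
  }

  eta_u <- unname(u[records$surgeon_id])
  eta_ae <- truth_linear_predictor(records, config$true_coefs_ae90) + eta_u
  eta_re <- truth_linear_predictor(records, config$true_coefs_reop2y) + eta_u
  b0_ae <- calibrate_intercept(eta_ae, NULL, config$target_rate_ae90)
  b0_re <- calibrate_intercept(eta_re, NULL, config$target_rate_reop2y)
  p_ae <- plogis(b0_ae + eta_ae)
  p_re <- plogis(b0_re + eta_re)
  records$ae90 <- rbinom(nrow(records), 1, p_ae)
  records$reop2y <- rbinom(nrow(records), 1, p_re)

  truth <- list(
    intercepts = c(ae90 = b0_ae, reop2y = b0_re),
    coefs = list(ae90 = config$true_coefs_ae90,
                 reop2y = config$true_coefs_reop2y),
    surgeon_effects = tibble::tibble(
      surgeon_id = ids, effect = unname(u[ids]),
      case_mix_severity = unname(severity[ids])
    ),
    probs = tibble::tibble(record_id = records$record_id,
                           p_ae90 = p_ae, p_reop2y = p_re)
  )

  # MCAR missingness applied last: the truth above used complete values
  if (config$miss_bmi > 0) {
    records$bmi[runif(nrow(records)) < config$miss_bmi] <- NA_real_
  }
  if (config$miss_asa > 0) {
    records$asa[runif(nrow(records)) < config$miss_asa] <- NA
  }

  structure(list(cohort = as_cohort(records), truth = truth, config = config),
            class = "synthetic_registry")
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("Synthetic surgical registry\n")
  cat("  surgeries:", nrow(x$cohort), " surgeons:",
      length(unique(x$cohort$surgeon_id)), " years:",
      paste(range(x$cohort$year), collapse = "-"), "\n")
  cat("  ae90 rate:", signif(mean(x$cohort$ae90), 3),
      " reop2y rate:", signif(mean(x$cohort$reop2y), 3), "\n")
  invisible(x)
}
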