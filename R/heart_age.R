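#' Reference-"normal" profile policy
#'
#' The Heart Age of a user is the age at which a person with all risk
#' factors at reference-"normal" values has the same predicted 10-year
#' CVD risk.  This policy object holds those reference values:
#' non-smoking, non-diabetic, SBP 125 mmHg (130 mmHg from age 60),
#' TC 180 mg/dl and HDL 45 mg/dl.  For equations that use TC without
#' HDL the reference TC is raised to 200 mg/dl to increase their
#' sensitivity.  The risk equations' source cohort defines no "normal"
#' BMI; the default 22.5 kg/m2 is the midpoint of the conventional
#' normal band (18.5–25) and is configurable.
#'
#' @param tc_ref reference total cholesterol, mg/dl.
#' @param tc_ref_no_hdl reference TC for models without HDL, mg/dl.
#' @param hdl_ref reference HDL cholesterol, mg/dl.
#' @param sbp_ref_under60,sbp_ref_60plus reference SBP below/at-or-above
#'   age 60, mmHg.
#' @param bmi_ref reference BMI, kg/m2 (not sourced from the risk
#'   equations' cohort; see Details).
#' @return An object of class `reference_policy`.
#' @export
reference_policy <- function(tc_ref = 180, tc_ref_no_hdl = 200,
                             hdl_ref = 45, sbp_ref_under60 = 125,
                             sbp_ref_60plus = 130, bmi_ref = 22.5) {
  ranges <- validity_ranges()
  vals <- c(tc_ref = tc_ref, tc_ref_no_hdl = tc_ref_no_hdl,
            hdl_ref = hdl_ref, sbp_ref_under60 = sbp_ref_under60,
            sbp_ref_60plus = sbp_ref_60plus, bmi_ref = bmi_ref)
  rng <- list(tc_ref = ranges$tc, tc_ref_no_hdl = ranges$tc,
              hdl_ref = ranges$hdl, sbp_ref_under60 = ranges$sbp,
              sbp_ref_60plus = ranges$sbp, bmi_ref = ranges$bmi)
  for (nm in names(vals))
    if (vals[[nm]] < rng[[nm]][1] || vals[[nm]] > rng[[nm]][2])
      stop_heartage(sprintf("%s = %g outside its validity range",
                            nm, vals[[nm]]),
                    "heartage_config_error")
  structure(list(tc_ref = tc_ref, tc_ref_no_hdl = tc_ref_no_hdl,
                 hdl_ref = hdl_ref, sbp_ref_under60 = sbp_ref_under60,
                 sbp_ref_60plus = sbp_ref_60plus,
                 smoker_ref = FALSE, diabetic_ref = FALSE,
                 bp_treated_ref = FALSE, bmi_ref = bmi_ref),
            class = "reference_policy")
}

#' Heart Age capping policy
#'
#' Heart Age is capped to within `max_delta` years of chronological
#' age and to the absolute range `[floor, ceiling]`, alerting users of
#' the need for change without creating alarm.
#'
#' @param max_delta maximum |Heart Age - age| in years.
#' @param floor,ceiling absolute Heart Age bounds in years.
#' @return An object of class `cap_policy`.
#' @export
cap_policy <- function(max_delta = 15, floor = 18, ceiling = 80) {
  if (!(floor < ceiling) || !(max_delta > 0))
    stop_heartage("cap policy requires floor < ceiling and max_delta > 0",
                  "heartage_config_error")
  structure(list(max_delta = max_delta, floor = floor, ceiling = ceiling),
            class = "cap_policy")
}

# Reference covariate values for a given model at a vector of ages.
# Returns a data frame with exactly the covariates the model needs.
reference_covariates <- function(age, model, policy) {
  uses_hdl <- "hdl" %in% model$terms$name
  sbp_ref <- ifelse(age >= 60, policy$sbp_ref_60plus,
                    policy$sbp_ref_under60)
  data.frame(
    age = age,
    tc = if (uses_hdl) policy$tc_ref else policy$tc_ref_no_hdl,
    hdl = policy$hdl_ref,
    sbp = sbp_ref,
    bmi = policy$bmi_ref,
    smoker = as.numeric(policy$smoker_ref),
    diabetic = as.numeric(policy$diabetic_ref),
    bp_treated = policy$bp_treated_ref)
}

#' Reference-normal profile for an algorithm
#'
#' Builds the profile of a person of the given age with every risk
#' factor the algorithm uses at its reference-"normal" value.
#'
#' @param age age in years (18–80).
#' @param sex `"male"` or `"female"`.
#' @param algorithm an algorithm id (see [cox_risk_model]).
#' @param policy a [reference_policy()].
#' @return A [risk_profile()] carrying reference values only for the
#'   covariates the algorithm requires (others `NA`).
#' @export
reference_profile <- function(age, sex, algorithm,
                              policy = reference_policy()) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
      age < 18 || age > 80)
    stop_heartage("age must be in [18, 80]", "heartage_domain_error")
  algorithm <- match.arg(algorithm, ALGORITHM_IDS)
  measures <- ALGORITHM_MEASURES[[algorithm]]
  uses_hdl <- "hdl" %in% measures
  risk_profile(
    age = age, sex = sex,
    smoker = policy$smoker_ref, diabetic = policy$diabetic_ref,
    tc = if ("tc" %in% measures) {
      if (uses_hdl) policy$tc_ref else policy$tc_ref_no_hdl
    } else NA_real_,
    hdl = if (uses_hdl) policy$hdl_ref else NA_real_,
    sbp = if ("sbp" %in% measures) {
      if (age >= 60) policy$sbp_ref_60plus else policy$sbp_ref_under60
    } else NA_real_,
    bp_treated = policy$bp_treated_ref,
    bmi = if ("bmi" %in% measures) policy$bmi_ref else NA_real_)
}

#' Risk along the reference-normal age curve
#'
#' Ten-year risk of the reference-normal profile as a function of age,
#' vectorized over `age`.  This is the curve [invert_heart_age()]
#' inverts.  It is strictly increasing in age, with one upward step at
#' age 60 (the reference SBP switch) for SBP-bearing algorithms.
#'
#' @param age numeric vector of ages in years.
#' @param model a `cox_risk_model`.
#' @param policy a [reference_policy()].
#' @return Vector of probabilities.
#' @export
reference_risk <- function(age, model, policy = reference_policy()) {
  risk_from_lp(eval_lp(model, reference_covariates(age, model, policy)),
               model)
}

# Vectorized bisection of the reference risk curve.  Risks below the
# curve at age 18 (or above at 80) clamp to 18 (80) pre-cap; risks in
# the discontinuity gap at the age-60 reference-SBP step converge to
# 60.  52 halvings of the 62-year bracket put the bracket width below
# 2^-45 years, far inside the 0.01-year contract, and |risk error|
# below 1e-10 wherever the curve is continuous.
invert_heart_age_vec <- function(risk, model, policy) {
  if (any(!is.finite(risk) | risk <= 0 | risk >= 1))
    stop_heartage("risk must lie strictly inside (0, 1)",
                  "heartage_domain_error")
  lo <- rep(18, length(risk))
  hi <- rep(80, length(risk))
  r_lo <- reference_risk(lo, model, policy)
  r_hi <- reference_risk(hi, model, policy)
  below <- risk <= r_lo
  above <- risk >= r_hi
  for (i in seq_len(52)) {
    mid <- (lo + hi) / 2
    r_mid <- reference_risk(mid, model, policy)
    go_up <- r_mid < risk
    lo[go_up] <- mid[go_up]
    hi[!go_up] <- mid[!go_up]
  }
  out <- (lo + hi) / 2
  out[below] <- 18
  out[above] <- 80
  out
}

#' Invert a 10-year risk into an (uncapped) Heart Age
#'
#' Finds the age at which the reference-normal profile of the same sex
#' would have the given 10-year risk, by bisection over ages 18–80.
#' Risks falling inside the discontinuity gap of the reference curve
#' at age 60 (where the reference SBP steps from 125 to 130 mmHg)
#' resolve to exactly 60; risks below the curve at 18 (or above at 80)
#' return 18 (80), with final clamping left to [cap_heart_age()].
#'
#' @param risk 10-year risk, strictly inside (0, 1).
#' @param model the `cox_risk_model` whose reference curve to invert.
#' @param policy a [reference_policy()].
#' @return Uncapped Heart Age in real-valued years.
#' @export
invert_heart_age <- function(risk, model, policy = reference_policy()) {
  stopifnot(inherits(model, "cox_risk_model"))
  invert_heart_age_vec(risk, model, policy)
}

#' Cap a Heart Age
#'
#' Clamps an uncapped Heart Age to the window
#' `[max(floor, age - max_delta), min(ceiling, age + max_delta)]`.
#' Idempotent, and vectorized over both arguments.
#'
#' @param uncapped uncapped Heart Age, years.
#' @param chronological_age user's age, years.
#' @param policy a [cap_policy()].
#' @return Capped Heart Age, years (real-valued).
#' @export
cap_heart_age <- function(uncapped, chronological_age,
                          policy = cap_policy()) {
  lo <- pmax(policy$floor, chronological_age - policy$max_delta)
  hi <- pmin(policy$ceiling, chronological_age + policy$max_delta)
  pmin(pmax(uncapped, lo), hi)
}

#' Compute a user's Heart Age
#'
#' The full scoring pipeline for one profile: select the richest
#' computable algorithm from the available fields, evaluate the
#' 10-year CVD risk, invert the reference-normal risk curve to an
#' uncapped Heart Age, and cap.  Heart Age is kept real-valued
#' internally; the printed presentation rounds half-up to integer
#' years after capping.
#'
#' @param profile a [risk_profile()].
#' @param models a `risk_model_set` (default: bundled coefficients).
#' @param ref_policy a [reference_policy()].
#' @param cap a [cap_policy()].
#' @return An object of class `heart_age_result` with elements
#'   `risk_10y`, `heart_age_uncapped`, `heart_age` (capped,
#'   real-valued), `heart_age_display` (integer years),
#'   `relative_heart_age` (capped Heart Age minus chronological age),
#'   `algorithm`, and `capped`.
#' @examples
#' p <- risk_profile(44, "male", smoker = TRUE, tc = 240, hdl = 38,
#'                   sbp = 148)
#' heart_age(p)
#' @export
heart_age <- function(profile, models = default_models(),
                      ref_policy = reference_policy(),
                      cap = cap_policy()) {
  stopifnot(inherits(profile, "risk_profile"))
  algorithm <- select_algorithm(!is.na(profile$tc), !is.na(profile$hdl),
                                !is.na(profile$sbp), !is.na(profile$bmi))
  model <- get_model(models, algorithm, profile$sex)
  risk <- ten_year_risk(profile, model)
  uncapped <- invert_heart_age(risk, model, ref_policy)
  capped_ha <- cap_heart_age(uncapped, profile$age, cap)
  structure(
    list(risk_10y = risk,
         heart_age_uncapped = uncapped,
         heart_age = capped_ha,
         heart_age_display = round_half_up(capped_ha),
         relative_heart_age = capped_ha - profile$age,
         chronological_age = profile$age,
         algorithm = algorithm,
         capped = round_half_up(capped_ha) != round_half_up(uncapped)),
    class = "heart_age_result")
}

#' @export
print.heart_age_result <- function(x, ...) {
  cat(sprintf("Heart Age: %d years (chronological age %s)\n",
              as.integer(x$heart_age_display),
              format(x$chronological_age)))
  cat(sprintf("  10-year CVD risk: %.1f%%  [algorithm %s]\n",
              100 * x$risk_10y, x$algorithm))
  cat(sprintf("  relative Heart Age: %+d years%s\n",
              as.integer(round_half_up(x$relative_heart_age)),
              if (x$capped) "  (capped)" else ""))
  invisible(x)
}

#' Score a cohort of validated profiles
#'
#' Vectorized batch scoring: for every row of a validated cohort
#' (canonical columns as produced by [validate_questionnaire()]),
#' selects the algorithm from field availability and computes 10-year
#' risk and capped Heart Age.  Rows with no computable algorithm get
#' `NA` results and `algorithm` `"NONE"`.
#'
#' @param data data frame with columns `age`, `sex`, `tc`, `hdl`,
#'   `sbp`, `bmi`, `smoker`, `diabetic`, `bp_treated` (physiological
#'   columns `NA` when unknown/invalid).
#' @param models a `risk_model_set`.
#' @param ref_policy a [reference_policy()].
#' @param cap a [cap_policy()].
#' @param algorithm optionally force one algorithm id for every row
#'   (rows missing its inputs error); used by the masking experiment.
#' @return `data` with columns `algorithm`, `risk_10y`,
#'   `heart_age_uncapped`, `heart_age` (capped, real-valued) and
#'   `relative_heart_age` appended.
#' @export
score_cohort <- function(data, models = default_models(),
                         ref_policy = reference_policy(),
                         cap = cap_policy(), algorithm = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("age", "sex", "tc", "hdl", "sbp", "bmi", "smoker",
            "diabetic", "bp_treated")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_heartage(paste0("cohort lacks columns: ",
                         paste(miss, collapse = ", ")),
                  "heartage_input_error")
  n <- nrow(data)
  if (is.null(algorithm)) {
    has <- function(col) !is.na(data[[col]])
    tc <- has("tc"); hdl <- has("hdl") & tc; sbp <- has("sbp")
    bmi <- has("bmi")
    alg <- rep(NA_character_, n)
    alg[tc & hdl & sbp] <- "FULL"
    alg[tc & hdl & !sbp] <- "ALT1_TC_HDL"
    alg[tc & !hdl & sbp & bmi] <- "ALT2_TC_SBP_BMI"
    alg[tc & !hdl & !sbp & bmi] <- "ALT3_TC_BMI"
    alg[!tc & sbp & bmi] <- "ALT4_SBP_BMI"
    alg[!tc & !sbp & bmi] <- "ALT5_BMI"
    alg[is.na(alg)] <- "NONE"
  } else {
    alg <- rep(match.arg(algorithm, ALGORITHM_IDS), n)
  }
  risk <- rep(NA_real_, n)
  uncapped <- rep(NA_real_, n)
  for (a in unique(alg[alg != "NONE"])) {
    for (sx in SEXES) {
      idx <- which(alg == a & data$sex == sx)
      if (!length(idx)) next
      model <- get_model(models, a, sx)
      sub <- data[idx, , drop = FALSE]
      sub$smoker <- as.numeric(sub$smoker)
      sub$diabetic <- as.numeric(sub$diabetic)
      lp <- eval_lp(model, sub)
      risk[idx] <- risk_from_lp(lp, model)
      uncapped[idx] <- invert_heart_age_vec(risk[idx], model, ref_policy)
    }
  }
  data$algorithm <- alg
  data$risk_10y <- risk
  data$heart_age_uncapped <- uncapped
  data$heart_age <- cap_heart_age(uncapped, data$age, cap)
  data$relative_heart_age <- data$heart_age - data$age
  data
}
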