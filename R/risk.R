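#' A single user's risk-factor profile
#'
#' Bundles the questionnaire-derived risk factors used by the risk
#' equations.  Physiological measures (`tc`, `hdl`, `sbp`, `bmi`) may
#' be `NA` when unknown; algorithm selection ([select_algorithm()])
#' picks the richest equation the available fields support.  Family
#' history and lipid-lowering medication are carried for
#' classification and awareness modelling but never enter the risk
#' equations.
#'
#' @param age chronological age in years (18–80).
#' @param sex `"male"` or `"female"`.
#' @param smoker,diabetic,family_history logical flags.
#' @param tc,hdl total and HDL cholesterol in mg/dl, or `NA`.
#' @param sbp systolic blood pressure in mmHg, or `NA`.
#' @param bp_treated logical; on antihypertensive medication.
#' @param chol_treated logical; on lipid-lowering medication.
#' @param bmi body-mass index in kg/m2, or `NA`.
#' @return An object of class `risk_profile`.
#' @examples
#' p <- risk_profile(55, "male", tc = 180, hdl = 45, sbp = 125)
#' ten_year_risk(p, get_model(default_models(), "FULL", "male"))
#' @export
risk_profile <- function(age, sex, smoker = FALSE, diabetic = FALSE,
                         family_history = FALSE, tc = NA_real_,
                         hdl = NA_real_, sbp = NA_real_,
                         bp_treated = FALSE, chol_treated = FALSE,
                         bmi = NA_real_) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
      age < 18 || age > 80)
    stop_heartage("age must be a single value in [18, 80]",
                  "heartage_domain_error")
  sex <- match.arg(sex, SEXES)
  stopifnot(is_flag(smoker), is_flag(diabetic), is_flag(family_history),
            is_flag(bp_treated), is_flag(chol_treated))
  structure(
    list(age = as.numeric(age), sex = sex, smoker = smoker,
         diabetic = diabetic, family_history = family_history,
         tc = as.numeric(tc), hdl = as.numeric(hdl),
         sbp = as.numeric(sbp), bp_treated = bp_treated,
         chol_treated = chol_treated, bmi = as.numeric(bmi)),
    class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "unknown" else format(v)
  cat(sprintf("Risk-factor profile: %s, age %s\n", x$sex, format(x$age)))
  cat(sprintf("  TC %s mg/dl, HDL %s mg/dl, SBP %s mmHg%s, BMI %s kg/m2\n",
              fmt(x$tc), fmt(x$hdl), fmt(x$sbp),
              if (isTRUE(x$bp_treated)) " (treated)" else "", fmt(x$bmi)))
  cat(sprintf("  smoker: %s, diabetic: %s, family history: %s\n",
              x$smoker, x$diabetic, x$family_history))
  invisible(x)
}

# Vectorized term evaluation over a data frame of canonical covariate
# columns.  Returns the n-vector of linear predictors.  Columns must be
# complete (no NA) for every covariate the model names.
eval_lp <- function(model, data) {
  n <- nrow(data)
  lp <- numeric(n)
  for (i in seq_len(nrow(model$terms))) {
    nm <- model$terms$name[i]
    x <- data[[nm]]
    if (is.null(x) || anyNA(x))
      stop_heartage(sprintf("missing required covariate '%s' for %s/%s",
                            nm, model$algorithm, model$sex),
                    "heartage_missing_input")
    tr <- model$terms$transform[i]
    if (tr == "log") {
      if (any(x <= 0))
        stop_heartage(sprintf("non-positive value for log-transformed '%s'",
                              nm),
                      "heartage_domain_error")
      x <- log(x)
    } else {
      x <- as.numeric(x)
    }
    treated <- model$terms$treated[i]
    if (!is.na(treated)) {
      bt <- data[["bp_treated"]]
      if (is.null(bt) || anyNA(bt))
        stop_heartage(sprintf(
          "missing required covariate 'bp_treated' for %s/%s",
          model$algorithm, model$sex),
          "heartage_missing_input")
      x <- x * as.numeric(bt == treated)
    }
    lp <- lp + model$terms$coefficient[i] * x
  }
  lp
}

profile_as_row <- function(profile) {
  data.frame(age = profile$age, tc = profile$tc, hdl = profile$hdl,
             sbp = profile$sbp, bmi = profile$bmi,
             smoker = as.numeric(profile$smoker),
             diabetic = as.numeric(profile$diabetic),
             bp_treated = profile$bp_treated)
}

#' Cox linear predictor for a profile
#'
#' Evaluates the model's linear predictor, the sum of coefficient
#' times transformed covariate over the model's terms.  For models
#' with a treated/untreated SBP split, only the variant matching the
#' profile's medication flag contributes.
#'
#' @param profile a [risk_profile()].
#' @param model a `cox_risk_model`.
#' @return A single dimensionless score.
#' @export
linear_predictor <- function(profile, model) {
  stopifnot(inherits(profile, "risk_profile"),
            inherits(model, "cox_risk_model"))
  if (profile$sex != model$sex)
    stop_heartage("profile sex does not match model sex",
                  "heartage_domain_error")
  eval_lp(model, profile_as_row(profile))
}

# Vectorized 10-year risk from a linear predictor vector.
risk_from_lp <- function(lp, model) {
  1 - model$s0_10 ^ exp(lp - model$mean_lp)
}

#' Ten-year CVD risk
#'
#' Computes the probability of a cardiovascular event within ten years
#' as `1 - S0(10)^exp(LP - meanLP)`, the standard Cox
#' proportional-hazards risk with baseline survival `S0(10)` evaluated
#' at the cohort-mean linear predictor.
#'
#' @inheritParams linear_predictor
#' @return A probability strictly inside (0, 1).
#' @export
ten_year_risk <- function(profile, model) {
  risk_from_lp(linear_predictor(profile, model), model)
}

#' Choose the richest computable risk algorithm
#'
#' Maps the availability pattern of the four physiological measures to
#' the algorithm the tool applies.  HDL without TC is ignored (treated
#' as lipids unknown): no equation consumes HDL alone, mirroring the
#' questionnaire's cholesterol dialogue which collects the two
#' together.
#'
#' @param tc,hdl,sbp,bmi logicals: is a valid value available?
#' @return An algorithm id (see [cox_risk_model]).  If no equation is
#'   computable (for instance TC present but HDL, SBP and BMI all
#'   absent) an error of class `heartage_uncomputable` is raised,
#'   mirroring the tool's exclusion of users with no usable values.
#' @export
select_algorithm <- function(tc, hdl, sbp, bmi) {
  stopifnot(is_flag(tc), is_flag(hdl), is_flag(sbp), is_flag(bmi))
  hdl <- hdl && tc            # HDL without TC is ignored
  out <-
    if (tc && hdl && sbp)      "FULL"
    else if (tc && hdl)        "ALT1_TC_HDL"
    else if (tc && sbp && bmi) "ALT2_TC_SBP_BMI"
    else if (tc && !sbp && bmi) "ALT3_TC_BMI"
    else if (!tc && sbp && bmi) "ALT4_SBP_BMI"
    else if (!tc && !sbp && bmi) "ALT5_BMI"
    else NA_character_
  if (is.na(out))
    stop_heartage(
      "no computable algorithm for this availability pattern",
      "heartage_uncomputable")
  out
}
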