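#' Configuration for the synthetic-cohort generator
#'
#' Defines the study conditions the generator emulates: the user base
#' of a web-based Heart Age self-assessment tool.  Defaults reproduce
#' the published marginal structure of that user base — female
#' fraction 56.03%; a bimodal age mixture peaking in the 20s (22.76%)
#' and 40s (23.99%) with a sharp post-60 decline (10.92% in the 60s,
#' 2.94% in the 70s); per-sex means/SDs for TC, HDL, SBP and BMI;
#' smoking 23.37%, diabetes 3.39%, family history 32.84% — together
#' with an awareness model whose per-measure log-odds are taken from
#' the published per-characteristic odds ratios and whose intercepts
#' are calibrated so marginal awareness approximates 22.53% (TC),
#' 6.97% (HDL) and 53.45% (SBP).  Physiological values are drawn from
#' truncated normals inside the validity ranges, linked by a Gaussian
#' copula with modest conventional correlations (the source reports
#' marginals only).  HDL awareness is modelled conditionally on TC
#' awareness, reflecting the questionnaire's joint cholesterol
#' dialogue.
#'
#' Pathology rates inject, with labels, the data defects the cleaning
#' cascade removes: default-age-20 rows, self-declared repeat users,
#' all-invalid physiological values, and duplicated records; default
#' rates mirror the published exclusion fractions.
#'
#' @param n number of users.
#' @param seed integer seed; generation is bit-reproducible given
#'   `(config, seed)`.
#' @param female_fraction probability a user is female.
#' @param age_weights decade weights (ages 21–29, 30–39, ..., 70–80),
#'   summing to 1; uniform within each decade.
#' @param tc,hdl,sbp,bmi per-sex `c(mean, sd)` lists.
#' @param smoker,diabetic,family_history,bp_treated,chol_treated
#'   prevalences.
#' @param copula 4x4 correlation matrix over (tc, hdl, sbp, bmi).
#' @param awareness per-measure coefficient vectors
#'   `c(intercept, age, diabetic, smoker, family_history)` on the
#'   log-odds scale; age is centered at 45 years.  The `hdl` model is
#'   conditional on TC awareness.
#' @param pathology rates `c(age20, repeat, invalid, duplicate)`.
#' @param country_weights named site-label weights (the optional
#'   country covariate for adjusted analyses).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n = 10000L, seed = 1L,
    female_fraction = 0.5603,
    age_weights = c(0.2276, 0.2139, 0.2399, 0.1800, 0.1092, 0.0294),
    tc = list(male = c(193.5, 44.0), female = c(197.7, 46.6)),
    hdl = list(male = c(61.6, 16.4), female = c(62.5, 15.1)),
    sbp = list(male = c(127.1, 13.3), female = c(122.4, 14.6)),
    bmi = list(male = c(26.3, 4.3), female = c(25.6, 5.2)),
    smoker = 0.2337, diabetic = 0.0339, family_history = 0.3284,
    bp_treated = 0.10, chol_treated = 0.08,
    copula = default_copula(),
    awareness = default_awareness_model(),
    pathology = c(age20 = 0.0959, repeat_user = 0.0426,
                  invalid = 0.0097, duplicate = 0.0387),
    country_weights = c(UK = 0.3119, DE = 0.1835, NL = 0.1833,
                        BE = 0.1501, FI = 0.0918, OTHER = 0.0794)) {
  if (n < 1) stop_heartage("n must be positive", "heartage_config_error")
  if (abs(sum(age_weights) - 1) > 1e-6)
    stop_heartage("age_weights must sum to 1", "heartage_config_error")
  probs <- c(female_fraction, smoker, diabetic, family_history,
             bp_treated, chol_treated, pathology)
  if (any(probs < 0 | probs > 1))
    stop_heartage("probabilities must lie in [0, 1]",
                  "heartage_config_error")
  for (par in list(tc, hdl, sbp, bmi))
    if (any(vapply(par, `[`, numeric(1), 2) < 0))
      stop_heartage("SDs must be non-negative", "heartage_config_error")
  ev <- eigen(copula, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    stop_heartage("copula matrix is not positive semi-definite",
                  "heartage_config_error")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         female_fraction = female_fraction, age_weights = age_weights,
         tc = tc, hdl = hdl, sbp = sbp, bmi = bmi, smoker = smoker,
         diabetic = diabetic, family_history = family_history,
         bp_treated = bp_treated, chol_treated = chol_treated,
         copula = copula, awareness = awareness, pathology = pathology,
         country_weights = country_weights),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_copula <- function() {
  R <- diag(4)
  dimnames(R) <- list(c("tc", "hdl", "sbp", "bmi"),
                      c("tc", "hdl", "sbp", "bmi"))
  R["tc", "sbp"] <- R["sbp", "tc"] <- 0.15
  R["tc", "bmi"] <- R["bmi", "tc"] <- 0.15
  R["sbp", "bmi"] <- R["bmi", "sbp"] <- 0.25
  R["hdl", "bmi"] <- R["bmi", "hdl"] <- -0.30
  R["hdl", "tc"] <- R["tc", "hdl"] <- -0.05
  R["hdl", "sbp"] <- R["sbp", "hdl"] <- -0.05
  R
}

# Log-odds per measure: slopes are logs of published per-characteristic
# odds ratios (age per year, diabetes, current smoking, family
# history); intercepts calibrated once against the default covariate
# mixture so marginal awareness is about 22.53% (TC), 6.97% (HDL,
# conditional model targeting the marginal among the TC-aware) and
# 53.45% (SBP).  See tools/refit-partial-models.R for the calibration.
#' @rdname cohort_config
#' @export
default_awareness_model <- function() {
  list(
    tc = c(intercept = -1.37395, age = log(1.07), diabetic = log(1.74),
           smoker = log(0.67), family_history = log(1.43)),
    hdl = c(intercept = -1.35516, age = log(1.06), diabetic = log(1.48),
            smoker = log(0.52), family_history = log(1.26)),
    sbp = c(intercept = 0.27124, age = log(1.05), diabetic = log(1.47),
            smoker = log(0.71), family_history = log(1.22)))
}

AGE_DECADES <- list(c(21, 29), c(30, 39), c(40, 49), c(50, 59),
                    c(60, 69), c(70, 80))

awareness_lp <- function(coefs, age, diabetic, smoker, family_history) {
  coefs[["intercept"]] + coefs[["age"]] * (age - 45) +
    coefs[["diabetic"]] * diabetic + coefs[["smoker"]] * smoker +
    coefs[["family_history"]] * family_history
}

#' Generate a synthetic user cohort
#'
#' Draws `config$n` questionnaire rows under the configured marginal
#' distributions, awareness model and pathology rates (see
#' [cohort_config()]).  Latent truth columns, prefixed `.truth_`,
#' record the pre-blanking physiological values, the awareness-model
#' linear predictors and the pathology labels; they exist for
#' generator validation only and never feed the scoring pipeline.
#'
#' @param config a [cohort_config()].
#' @return Data frame in the batch questionnaire schema plus
#'   `.truth_*` columns.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  sex <- ifelse(stats::runif(n) < config$female_fraction,
                "female", "male")
  decade <- sample.int(length(AGE_DECADES), n, replace = TRUE,
                       prob = config$age_weights)
  lo <- vapply(AGE_DECADES, `[`, numeric(1), 1)[decade]
  hi <- vapply(AGE_DECADES, `[`, numeric(1), 2)[decade]
  age <- floor(stats::runif(n, lo, hi + 1))
  age <- pmin(age, hi)

  # physiological values: Gaussian copula over (tc, hdl, sbp, bmi)
  z <- matrix(stats::rnorm(4 * n), n, 4) %*% chol(config$copula)
  u <- stats::pnorm(z)
  ranges <- validity_ranges()
  draw <- function(col, par) {
    m <- ifelse(sex == "male", par$male[1], par$female[1])
    s <- ifelse(sex == "male", par$male[2], par$female[2])
    r <- ranges[[col]]
    ifelse(s == 0, m, qtruncnorm(u[, col], m, s, r[1], r[2]))
  }
  colnames(u) <- c("tc", "hdl", "sbp", "bmi")
  tc <- draw("tc", config$tc)
  hdl <- draw("hdl", config$hdl)
  sbp <- draw("sbp", config$sbp)
  bmi <- draw("bmi", config$bmi)

  smoker <- stats::runif(n) < config$smoker
  diabetic <- stats::runif(n) < config$diabetic
  family_history <- stats::runif(n) < config$family_history
  bp_treated <- stats::runif(n) < config$bp_treated
  chol_treated <- stats::runif(n) < config$chol_treated

  lp_tc <- awareness_lp(config$awareness$tc, age, diabetic, smoker,
                        family_history)
  lp_hdl <- awareness_lp(config$awareness$hdl, age, diabetic, smoker,
                         family_history)
  lp_sbp <- awareness_lp(config$awareness$sbp, age, diabetic, smoker,
                         family_history)
  aware_tc <- stats::runif(n) < stats::plogis(lp_tc)
  # HDL awareness is modelled among the TC-aware only
  aware_hdl <- aware_tc & (stats::runif(n) < stats::plogis(lp_hdl))
  aware_sbp <- stats::runif(n) < stats::plogis(lp_sbp)

  height <- round(ifelse(sex == "male", stats::rnorm(n, 178, 7),
                         stats::rnorm(n, 165, 6.5)))
  weight <- round(bmi * (height / 100)^2, 1)

  usage_date <- as.character(
    as.Date("2009-07-01") +
      floor(stats::runif(n, 0, 914)))  # through 2011-12-31
  country <- sample(names(config$country_weights), n, replace = TRUE,
                    prob = config$country_weights)

  cohort <- data.frame(
    age = age, sex = sex, height = height, weight = weight,
    tc = ifelse(aware_tc, round(tc), NA_real_),
    hdl = ifelse(aware_hdl, round(hdl), NA_real_),
    sbp = ifelse(aware_sbp, round(sbp), NA_real_),
    smoker = smoker, diabetic = diabetic,
    family_history = family_history, bp_treated = bp_treated,
    chol_treated = chol_treated,
    aware_tc = aware_tc, aware_hdl = aware_hdl, aware_sbp = aware_sbp,
    repeat_user = FALSE, usage_date = usage_date, country = country,
    .truth_tc = tc, .truth_hdl = hdl, .truth_sbp = sbp,
    .truth_bmi = bmi,
    .truth_lp_tc = lp_tc, .truth_lp_hdl = lp_hdl,
    .truth_lp_sbp = lp_sbp,
    .truth_pathology = "none",
    stringsAsFactors = FALSE)
  inject_pathologies(cohort, config$pathology)
}

#' Inject labeled data pathologies
#'
#' Marks a multinomially-drawn partition of rows with one pathology
#' each: `age20` rows get the suspicious default age of 20;
#' `repeat_user` rows self-declare prior use; `invalid` rows get every
#' physiological value pushed outside its validity range (making the
#' row uncomputable); `duplicate` rows become exact copies of another
#' retained row, so the deduplication key (usage date, BMI, TC, HDL,
#' SBP, Heart Age, 10-year risk) matches exactly.  Labels are written
#' to `.truth_pathology`.  Uses the current RNG state.
#'
#' @param cohort questionnaire data frame (with or without `.truth_*`
#'   columns).
#' @param rates named rates `c(age20, repeat_user, invalid, duplicate)`
#'   in `[0, 1]`, summing to at most 1.
#' @return The cohort with pathologies applied and labeled.
#' @export
inject_pathologies <- function(cohort, rates) {
  stopifnot(is.data.frame(cohort))
  rates <- rates[c("age20", "repeat_user", "invalid", "duplicate")]
  if (anyNA(rates) || any(rates < 0) || sum(rates) > 1)
    stop_heartage("pathology rates must be in [0,1] and sum to <= 1",
                  "heartage_config_error")
  n <- nrow(cohort)
  if (is.null(cohort$.truth_pathology))
    cohort$.truth_pathology <- "none"
  lab <- sample(c(names(rates), "none"), n, replace = TRUE,
                prob = c(rates, 1 - sum(rates)))
  cohort$.truth_pathology <- lab
  cohort$age[lab == "age20"] <- 20L
  cohort$repeat_user[lab == "repeat_user"] <- TRUE
  inv <- which(lab == "invalid")
  if (length(inv)) {
    cohort$tc[inv] <- ifelse(is.na(cohort$tc[inv]), NA, 500)
    cohort$hdl[inv] <- ifelse(is.na(cohort$hdl[inv]), NA, 10)
    cohort$sbp[inv] <- ifelse(is.na(cohort$sbp[inv]), NA, 250)
    # weight implying BMI of 50 — outside the validity range
    cohort$weight[inv] <- round(50 * (cohort$height[inv] / 100)^2, 1)
  }
  dup <- which(lab == "duplicate")
  src_pool <- which(lab == "none")
  if (length(dup)) {
    if (!length(src_pool))
      stop_heartage("cannot duplicate: no clean rows to copy",
                    "heartage_config_error")
    src <- src_pool[sample.int(length(src_pool), length(dup),
                               replace = TRUE)]
    keep_lab <- cohort$.truth_pathology[dup]
    cohort[dup, ] <- cohort[src, ]
    cohort$.truth_pathology[dup] <- keep_lab
  }
  cohort
}
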