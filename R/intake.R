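#' Validity ranges for physiological measures
#'
#' Values outside these clinical-judgment ranges are treated as
#' missing, not rejected: SBP 80–220 mmHg, TC 77–423 mg/dl,
#' HDL 25–90 mg/dl, BMI 15–45 kg/m2.  Both endpoints are valid.
#'
#' @return Named list of `c(lower, upper)` vectors for `sbp`, `tc`,
#'   `hdl`, `bmi`.
#' @export
validity_ranges <- function() {
  list(sbp = c(80, 220), tc = c(77, 423), hdl = c(25, 90),
       bmi = c(15, 45))
}

#' Risk-factor classification thresholds
#'
#' Dichotomization cut-points: high TC at TC >= 240 mg/dl, low HDL at
#' HDL <= 40 mg/dl, high SBP at SBP >= 140 mmHg, overweight at
#' BMI >= 25 and obesity at BMI >= 30 kg/m2.
#'
#' @return Named list of scalar thresholds.
#' @export
classification_thresholds <- function() {
  list(high_tc = 240, low_hdl = 40, high_sbp = 140,
       overweight = 25, obese = 30)
}

MGDL_PER_MMOLL <- 38.67   # cholesterol: mg/dl per mmol/l
CM_PER_INCH <- 2.54
KG_PER_LB <- 0.45359237

#' Convert questionnaire units to canonical units
#'
#' Canonical units are cm, kg, mg/dl and mmHg.  Cholesterol reported
#' in mmol/l is multiplied by 38.67 mg/dl per mmol/l; height in inches
#' by 2.54 cm; weight in pounds by 0.45359237 kg.  Already-canonical
#' inputs pass through unchanged.  Unit tags are read from optional
#' columns `tc_units`/`hdl_units` (`"mgdl"` or `"mmoll"`),
#' `height_units` (`"cm"`/`"inch"`) and `weight_units` (`"kg"`/`"lb"`),
#' with per-file defaults supplied as arguments.
#'
#' @param raw data frame of raw questionnaire rows.
#' @param tc_units,hdl_units,height_units,weight_units defaults applied
#'   where no per-row unit column exists.
#' @return `raw` with measurement columns in canonical units and unit
#'   columns normalized to the canonical tags.
#' @export
convert_units <- function(raw, tc_units = "mgdl", hdl_units = tc_units,
                          height_units = "cm", weight_units = "kg") {
  stopifnot(is.data.frame(raw))
  conv <- function(values, units, allowed, factors) {
    bad <- !units %in% allowed
    if (any(bad))
      stop_heartage(paste0("unknown unit tag: ",
                           paste(unique(units[bad]), collapse = ", ")),
                    "heartage_input_error")
    values * factors[units]
  }
  units_col <- function(col, default) {
    u <- raw[[col]] %||% rep(default, nrow(raw))
    u[is.na(u)] <- default
    u
  }
  if (!is.null(raw$tc))
    raw$tc <- conv(raw$tc, units_col("tc_units", tc_units),
                   c("mgdl", "mmoll"),
                   c(mgdl = 1, mmoll = MGDL_PER_MMOLL))
  if (!is.null(raw$hdl))
    raw$hdl <- conv(raw$hdl, units_col("hdl_units", hdl_units),
                    c("mgdl", "mmoll"),
                    c(mgdl = 1, mmoll = MGDL_PER_MMOLL))
  if (!is.null(raw$height))
    raw$height <- conv(raw$height, units_col("height_units", height_units),
                       c("cm", "inch"), c(cm = 1, inch = CM_PER_INCH))
  if (!is.null(raw$weight))
    raw$weight <- conv(raw$weight, units_col("weight_units", weight_units),
                       c("kg", "lb"), c(kg = 1, lb = KG_PER_LB))
  for (col in c("tc_units", "hdl_units"))
    if (!is.null(raw[[col]])) raw[[col]] <- "mgdl"
  if (!is.null(raw$height_units)) raw$height_units <- "cm"
  if (!is.null(raw$weight_units)) raw$weight_units <- "kg"
  raw
}

#' Body-mass index from self-reported height and weight
#'
#' @param height_cm height in cm.
#' @param weight_kg weight in kg.
#' @return BMI in kg/m2 (`NA` propagates).
#' @export
derive_bmi <- function(height_cm, weight_kg) {
  bad <- (!is.na(height_cm) & height_cm <= 0) |
    (!is.na(weight_kg) & weight_kg <= 0)
  if (any(bad))
    stop_heartage("height and weight must be positive",
                  "heartage_input_error")
  weight_kg / (height_cm / 100)^2
}

#' Validate a canonical questionnaire into risk-factor profiles
#'
#' Applies, per row: the awareness gate (a physiological value whose
#' "Do you know ...?" flag is `FALSE` is treated as absent), BMI
#' derivation from height/weight when no `bmi` column exists, and
#' validity screening (values beyond the ranges become missing, not
#' rejected; endpoints are valid).  A row with all four of TC, HDL,
#' SBP and BMI missing afterwards is flagged uncomputable.
#' Idempotent on its own output.
#'
#' @param raw data frame in canonical units (see [convert_units()]).
#' @param ranges a [validity_ranges()] list.
#' @return Data frame with canonical profile columns (`age`, `sex`,
#'   `tc`, `hdl`, `sbp`, `bmi`, `smoker`, `diabetic`,
#'   `family_history`, `bp_treated`, `chol_treated`) plus a logical
#'   `uncomputable` column; other input columns are carried through.
#' @export
validate_questionnaire <- function(raw, ranges = validity_ranges()) {
  stopifnot(is.data.frame(raw))
  gate <- function(values, aware) {
    if (!is.null(aware)) values[!is.na(aware) & !aware] <- NA_real_
    values
  }
  raw$tc <- gate(raw$tc %||% rep(NA_real_, nrow(raw)), raw$aware_tc)
  raw$hdl <- gate(raw$hdl %||% rep(NA_real_, nrow(raw)), raw$aware_hdl)
  raw$sbp <- gate(raw$sbp %||% rep(NA_real_, nrow(raw)), raw$aware_sbp)
  if (is.null(raw$bmi))
    raw$bmi <- derive_bmi(raw$height, raw$weight)
  for (m in c("tc", "hdl", "sbp", "bmi")) {
    r <- ranges[[m]]
    x <- raw[[m]]
    x[!is.na(x) & (x < r[1] | x > r[2])] <- NA_real_
    raw[[m]] <- x
  }
  for (fl in c("smoker", "diabetic", "family_history", "bp_treated",
               "chol_treated"))
    if (is.null(raw[[fl]])) raw[[fl]] <- FALSE
  raw$uncomputable <- is.na(raw$tc) & is.na(raw$hdl) & is.na(raw$sbp) &
    is.na(raw$bmi)
  raw
}

#' Classify risk factors and count unhealthy ones
#'
#' Emits the dichotomous flags `current_smoker`, `overweight`,
#' `obese`, `diabetic`, `high_tc`, `low_hdl`, `high_sbp`,
#' `family_history` and a count of unhealthy risk factors.  A flag on
#' a missing measurement is `NA`, never `FALSE`, and contributes
#' nothing to the count.  The count's membership (configurable via
#' `count_members`) is smoking, overweight, diabetes, high TC, low
#' HDL, high SBP and family history; obesity is excluded as subsumed
#' by overweight.
#'
#' @param profile validated data frame (see
#'   [validate_questionnaire()]); one or more rows.
#' @param thresholds a [classification_thresholds()] list.
#' @param count_members flags included in the unhealthy count.
#' @return `profile` with flag columns and `unhealthy_count` appended.
#' @export
classify_risk_factors <- function(profile,
                                  thresholds = classification_thresholds(),
                                  count_members = c("current_smoker",
                                                    "overweight",
                                                    "diabetic", "high_tc",
                                                    "low_hdl", "high_sbp",
                                                    "family_history")) {
  stopifnot(is.data.frame(profile))
  profile$current_smoker <- as.logical(profile$smoker)
  profile$overweight <- profile$bmi >= thresholds$overweight
  profile$obese <- profile$bmi >= thresholds$obese
  profile$high_tc <- profile$tc >= thresholds$high_tc
  profile$low_hdl <- profile$hdl <= thresholds$low_hdl
  profile$high_sbp <- profile$sbp >= thresholds$high_sbp
  profile$diabetic <- as.logical(profile$diabetic)
  profile$family_history <- as.logical(profile$family_history)
  cnt <- rep(0L, nrow(profile))
  for (m in count_members)
    cnt <- cnt + ifelse(is.na(profile[[m]]), 0L, as.integer(profile[[m]]))
  profile$unhealthy_count <- cnt
  profile
}

QUESTIONNAIRE_COLUMNS <- c(
  "age", "sex", "height", "weight", "tc", "hdl", "sbp", "smoker",
  "diabetic", "family_history", "bp_treated", "chol_treated",
  "aware_tc", "aware_hdl", "aware_sbp", "repeat_user", "usage_date",
  "country")

#' Read or write the batch questionnaire CSV
#'
#' One row per user; empty cells are missing.  Columns: `age`, `sex`
#' (`male`/`female`), `height` (cm), `weight` (kg), `tc`, `hdl`
#' (mg/dl), `sbp` (mmHg), logical `smoker`, `diabetic`,
#' `family_history`, `bp_treated`, `chol_treated`, `aware_tc`,
#' `aware_hdl`, `aware_sbp`, `repeat_user`, plus `usage_date`
#' (ISO 8601) and `country`.  Optional per-row unit columns
#' (`tc_units`, `hdl_units`, `height_units`, `weight_units`) override
#' the per-file defaults passed through to [convert_units()].
#'
#' @param path CSV path.
#' @param ... defaults forwarded to [convert_units()] (for instance
#'   `tc_units = "mmoll"`).
#' @return `read_questionnaire()`: a canonical-unit data frame.
#' @export
read_questionnaire <- function(path, ...) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  miss <- setdiff(c("age", "sex"), names(raw))
  if (length(miss))
    stop_heartage(paste0("questionnaire CSV lacks columns: ",
                         paste(miss, collapse = ", ")),
                  "heartage_input_error")
  for (fl in c("smoker", "diabetic", "family_history", "bp_treated",
               "chol_treated", "aware_tc", "aware_hdl", "aware_sbp",
               "repeat_user"))
    if (!is.null(raw[[fl]])) raw[[fl]] <- as.logical(raw[[fl]])
  convert_units(raw, ...)
}

#' @param cohort data frame of questionnaire rows.
#' @rdname read_questionnaire
#' @export
write_questionnaire <- function(cohort, path) {
  keep <- intersect(c(QUESTIONNAIRE_COLUMNS, "bmi"), names(cohort))
  utils::write.csv(cohort[, keep], path, row.names = FALSE, na = "")
  invisible(path)
}
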