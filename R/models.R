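#' Cox proportional-hazards risk equations for 10-year CVD risk
#'
#' A `cox_risk_model` holds one sex-specific risk equation: a set of
#' covariate terms (each a transform, a coefficient and, for systolic
#' blood pressure, an optional treated/untreated variant), the cohort
#' mean linear predictor and the 10-year baseline survival.  Twelve
#' models — six algorithms by two sexes — form a [risk_model_set] and
#' are loaded from a structured YAML coefficient file so that an
#' alternative coefficient source can be slotted in without code
#' changes.
#'
#' The six algorithms differ in which physiological measures they
#' consume:
#'
#' * `FULL` — total cholesterol (TC), HDL cholesterol and systolic
#'   blood pressure (SBP); the lipid-based equation.
#' * `ALT1_TC_HDL` — TC and HDL, no blood pressure.
#' * `ALT2_TC_SBP_BMI` — TC, SBP and body-mass index (BMI), no HDL.
#' * `ALT3_TC_BMI` — TC and BMI.
#' * `ALT4_SBP_BMI` — SBP and BMI; the office-based (non-laboratory)
#'   equation.
#' * `ALT5_BMI` — BMI only.
#'
#' All models additionally use log(age), current smoking and diabetes.
#' Models containing SBP carry separate coefficients for treated and
#' untreated blood pressure, switched by the antihypertensive
#' medication flag.
#'
#' @name cox_risk_model
#' @aliases risk_model_set
NULL

ALGORITHM_IDS <- c("FULL", "ALT1_TC_HDL", "ALT2_TC_SBP_BMI",
                   "ALT3_TC_BMI", "ALT4_SBP_BMI", "ALT5_BMI")
SEXES <- c("male", "female")
TRANSFORMS <- c("log", "identity", "indicator")

# Which physiological measures each algorithm consumes (besides age,
# smoking and diabetes, which every model uses).
ALGORITHM_MEASURES <- list(
  FULL            = c("tc", "hdl", "sbp"),
  ALT1_TC_HDL     = c("tc", "hdl"),
  ALT2_TC_SBP_BMI = c("tc", "sbp", "bmi"),
  ALT3_TC_BMI     = c("tc", "bmi"),
  ALT4_SBP_BMI    = c("sbp", "bmi"),
  ALT5_BMI        = "bmi"
)

new_cox_risk_model <- function(algorithm, sex, terms, mean_lp, s0_10,
                               version = "unversioned") {
  entry <- paste0(algorithm, "/", sex)
  if (!algorithm %in% ALGORITHM_IDS)
    stop_heartage(sprintf("unknown algorithm id '%s'", algorithm),
                  "heartage_config_error")
  if (!sex %in% SEXES)
    stop_heartage(sprintf("%s: unknown sex '%s'", entry, sex),
                  "heartage_config_error")
  stopifnot(is.data.frame(terms),
            all(c("name", "transform", "coefficient", "treated") %in%
                  names(terms)))
  if (!all(terms$transform %in% TRANSFORMS))
    stop_heartage(sprintf("%s: unknown transform", entry),
                  "heartage_config_error")
  if (!all(is.finite(terms$coefficient)))
    stop_heartage(sprintf("%s: non-finite coefficient", entry),
                  "heartage_config_error")
  if (!is.numeric(mean_lp) || !is.finite(mean_lp))
    stop_heartage(sprintf("%s: non-finite mean linear predictor", entry),
                  "heartage_config_error")
  if (!is.numeric(s0_10) || !is.finite(s0_10) || s0_10 <= 0 || s0_10 >= 1)
    stop_heartage(
      sprintf("%s: baseline 10-year survival %.4g outside (0, 1)",
              entry, s0_10),
      "heartage_config_error")
  measures <- intersect(unique(terms$name), c("tc", "hdl", "sbp", "bmi"))
  expected <- ALGORITHM_MEASURES[[algorithm]]
  if (!setequal(measures, expected))
    stop_heartage(
      sprintf("%s: term covariates {%s} do not match the algorithm's {%s}",
              entry, paste(measures, collapse = ","),
              paste(expected, collapse = ",")),
      "heartage_config_error")
  structure(
    list(algorithm = algorithm, sex = sex, terms = terms,
         mean_lp = mean_lp, s0_10 = s0_10, version = version),
    class = "cox_risk_model")
}

#' @export
print.cox_risk_model <- function(x, ...) {
  cat(sprintf("Cox 10-year CVD risk model [%s, %s]\n", x$algorithm, x$sex))
  cat(sprintf("  baseline survival S0(10) = %.5f, mean LP = %.4f\n",
              x$s0_10, x$mean_lp))
  trt <- ifelse(is.na(x$terms$treated), "",
                ifelse(x$terms$treated, " [treated]", " [untreated]"))
  cat(sprintf("  %-10s %-9s %+.5f%s\n", x$terms$name, x$terms$transform,
              x$terms$coefficient, trt), sep = "")
  invisible(x)
}

#' Covariates a model requires from a risk-factor profile
#'
#' @param model a `cox_risk_model`.
#' @return Character vector of covariate names (`age`, `tc`, `hdl`,
#'   `sbp`, `bmi`, `smoker`, `diabetic`, and `bp_treated` for models
#'   with a treated/untreated SBP split).
#' @export
required_inputs <- function(model) {
  stopifnot(inherits(model, "cox_risk_model"))
  out <- unique(model$terms$name)
  if (any(!is.na(model$terms$treated))) out <- c(out, "bp_treated")
  out
}

#' Load risk models from a coefficient file
#'
#' Parses a YAML coefficient document into a validated set of twelve
#' `cox_risk_model` objects (six algorithms by two sexes).  The file's
#' `version` string is retained on the set and on every model for
#' provenance.
#'
#' @param path path to a YAML coefficient file.
#' @return A `risk_model_set`: a named list of models keyed
#'   `"<algorithm>.<sex>"`, with attributes `version`.
#' @seealso [default_models()] for the bundled coefficient set,
#'   [write_models()] for re-serialization.
#' @export
load_models <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$models))
    stop_heartage("coefficient file has no 'models' entry",
                  "heartage_config_error")
  version <- doc$version %||% "unversioned"
  models <- lapply(doc$models, function(m) {
    terms <- do.call(rbind, lapply(m$terms, function(t) {
      data.frame(name = t$name, transform = t$transform,
                 coefficient = as.numeric(t$coefficient),
                 treated = if (is.null(t$treated)) NA else
                   isTRUE(t$treated),
                 stringsAsFactors = FALSE)
    }))
    new_cox_risk_model(m$algorithm, m$sex, terms,
                       as.numeric(m$mean_linear_predictor),
                       as.numeric(m$baseline_survival_10y),
                       version = version)
  })
  names(models) <- vapply(models, function(m)
    paste(m$algorithm, m$sex, sep = "."), character(1))
  if (anyDuplicated(names(models)))
    stop_heartage("duplicate (algorithm, sex) entries in coefficient file",
                  "heartage_config_error")
  expected <- as.vector(outer(ALGORITHM_IDS, SEXES, paste, sep = "."))
  missing <- setdiff(expected, names(models))
  if (length(missing))
    stop_heartage(paste0("coefficient file is missing entries: ",
                         paste(missing, collapse = ", ")),
                  "heartage_config_error")
  structure(models[expected], class = "risk_model_set", version = version)
}

#' Serialize a risk-model set back to YAML
#'
#' `write_models()` followed by [load_models()] reproduces the set
#' exactly (coefficients are written with full precision).
#'
#' @param models a `risk_model_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  stopifnot(inherits(models, "risk_model_set"))
  doc <- list(
    version = attr(models, "version"),
    models = lapply(unname(models), function(m) {
      list(algorithm = m$algorithm, sex = m$sex,
           terms = lapply(seq_len(nrow(m$terms)), function(i) {
             t <- as.list(m$terms[i, ])
             out <- list(name = t$name, transform = t$transform,
                         coefficient = t$coefficient)
             if (!is.na(t$treated)) out$treated <- t$treated
             out
           }),
           mean_linear_predictor = m$mean_lp,
           baseline_survival_10y = m$s0_10)
    }))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

# Cache for the bundled model set.
.heartage_env <- new.env(parent = emptyenv())

#' Bundled default risk models
#'
#' Loads (and caches) the coefficient set shipped with the package:
#' published general-CVD Framingham coefficients for the FULL
#' (lipid-based) and ALT4 (office-based) equations, and refit
#' coefficients for the partial-lipid equations ALT1, ALT2, ALT3 and
#' ALT5 (see the package vignette for the refit procedure).
#'
#' @return A `risk_model_set`.
#' @export
default_models <- function() {
  if (is.null(.heartage_env$models)) {
    path <- system.file("extdata", "heartage-coefficients.yaml",
                        package = "heartage", mustWork = TRUE)
    .heartage_env$models <- load_models(path)
  }
  .heartage_env$models
}

#' @export
print.risk_model_set <- function(x, ...) {
  cat(sprintf("Set of %d Cox 10-year CVD risk models (version: %s)\n",
              length(x), attr(x, "version")))
  for (m in x)
    cat(sprintf("  %-16s %-6s  S0(10)=%.5f  meanLP=%.4f  (%d terms)\n",
                m$algorithm, m$sex, m$s0_10, m$mean_lp, nrow(m$terms)))
  invisible(x)
}

#' Fetch one model from a set
#'
#' @param models a `risk_model_set`.
#' @param algorithm algorithm id.
#' @param sex `"male"` or `"female"`.
#' @return The matching `cox_risk_model`.
#' @export
get_model <- function(models, algorithm, sex) {
  key <- paste(algorithm, sex, sep = ".")
  m <- models[[key]]
  if (is.null(m))
    stop_heartage(sprintf("no model for %s", key), "heartage_config_error")
  m
}
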