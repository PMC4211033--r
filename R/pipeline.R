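#' Clean a raw cohort with the documented exclusion cascade
#'
#' Applies, in this fixed order: (1) drop rows with the suspicious
#' default age of exactly 20; (2) restrict to ages 21–80; (3) drop
#' self-declared repeat users; (4) drop rows whose TC, HDL, SBP and
#' BMI are all missing or beyond the validity ranges (no Heart Age is
#' computable); (5) drop rows duplicated on the seven-field key
#' (usage date, BMI, TC, HDL, SBP, Heart Age, 10-year risk), keeping
#' the first occurrence.  Each row is counted under the first rule
#' that removes it, so the itemized exclusions plus the retained count
#' equal the input rows.  Re-running on cleaned output is a no-op.
#'
#' @param cohort data frame in the batch questionnaire schema.
#' @param models optional `risk_model_set`; when supplied, Heart Age
#'   and risk are scored so the duplicate key can include them (the
#'   tool's own dedup key).  Without models the key uses the raw
#'   fields only, which is equivalent for exact-copy duplicates.
#' @param ranges a [validity_ranges()] list.
#' @return A list with `cohort` (the retained, validated rows) and
#'   `report` (a `cleaning_report` of per-rule exclusion counts).
#' @export
clean_cohort <- function(cohort, models = NULL,
                         ranges = validity_ranges()) {
  stopifnot(is.data.frame(cohort))
  if (is.null(cohort$age) || is.null(cohort$sex))
    stop_heartage("cohort lacks the questionnaire schema (age, sex)",
                  "heartage_input_error")
  n_in <- nrow(cohort)

  drop_age20 <- !is.na(cohort$age) & cohort$age == 20
  cohort <- cohort[!drop_age20, , drop = FALSE]
  drop_range <- is.na(cohort$age) | cohort$age < 21 | cohort$age > 80
  cohort <- cohort[!drop_range, , drop = FALSE]
  rep_flag <- cohort$repeat_user %||% rep(FALSE, nrow(cohort))
  drop_repeat <- !is.na(rep_flag) & rep_flag
  cohort <- cohort[!drop_repeat, , drop = FALSE]

  cohort <- validate_questionnaire(cohort, ranges)
  drop_missing <- cohort$uncomputable
  cohort <- cohort[!drop_missing, , drop = FALSE]

  key_cols <- c("usage_date", "bmi", "tc", "hdl", "sbp")
  if (!is.null(models)) {
    scored <- score_cohort(cohort, models)
    cohort$heart_age <- scored$heart_age
    cohort$risk_10y <- scored$risk_10y
  }
  key_cols <- intersect(c(key_cols, "heart_age", "risk_10y"),
                        names(cohort))
  key <- do.call(paste, c(cohort[key_cols], sep = "\r"))
  drop_dup <- duplicated(key)
  cohort <- cohort[!drop_dup, , drop = FALSE]
  rownames(cohort) <- NULL

  report <- structure(
    list(input = n_in,
         excluded = c(age20 = sum(drop_age20),
                      age_out_of_range = sum(drop_range),
                      repeat_user = sum(drop_repeat),
                      all_physio_missing = sum(drop_missing),
                      duplicate = sum(drop_dup)),
         retained = nrow(cohort)),
    class = "cleaning_report")
  list(cohort = cohort, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report: %d rows in, %d retained\n",
              x$input, x$retained))
  lbl <- c(age20 = "default age 20",
           age_out_of_range = "age outside 21-80",
           repeat_user = "repeat users",
           all_physio_missing = "all physiological values missing/invalid",
           duplicate = "duplicate records")
  for (nm in names(x$excluded))
    cat(sprintf("  - %-42s %d\n", lbl[[nm]], x$excluded[[nm]]))
  invisible(x)
}

# ANCOVA-style adjusted means: predictions per stratum at the overall
# covariate means.  Covariate design columns (including factor
# indicators) are centered at their observed means, so the stratum
# coefficients of delta ~ 0 + stratum + centered covariates are the
# adjusted means directly.
adjusted_means <- function(delta, stratum, covariates) {
  stratum <- factor(stratum)
  df <- as.data.frame(covariates)
  if (ncol(df)) {
    X <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
    X <- scale(X, center = TRUE, scale = FALSE)
    fit <- stats::lm(delta ~ 0 + stratum + X)
  } else {
    fit <- stats::lm(delta ~ 0 + stratum)
  }
  cf <- summary(fit)$coefficients
  idx <- grep("^stratum", rownames(cf))
  data.frame(stratum = sub("^stratum", "", rownames(cf)[idx]),
             adjusted_mean = cf[idx, 1], se = cf[idx, 2],
             row.names = NULL)
}

#' The algorithm-masking experiment
#'
#' On the complete subsample (rows with valid values for all of TC,
#' HDL, SBP and BMI), recomputes Heart Age six times per user —
#' masking, for each alternative algorithm, exactly the inputs it
#' ignores — and compares relative Heart Age (Heart Age minus
#' chronological age) under each alternative against the full
#' algorithm.  A positive delta means the alternative overestimates
#' Heart Age.  Deltas are summarized overall and stratified by sex,
#' 10-year age band, and 10-year CVD risk category (from the
#' full-model risk), with covariate-adjusted means from a linear model
#' with age and sex (and country, when present) as covariates.
#'
#' @param cohort cleaned, validated cohort (see [clean_cohort()]).
#' @param models a `risk_model_set`.
#' @param ref_policy a [reference_policy()].
#' @param cap a [cap_policy()].
#' @param risk_breaks interior cut points (on the probability scale)
#'   of the risk categories; default bins <10%, 10–20%, >20%.
#' @param adjust covariate names for the adjusted means.
#' @return A `masking_report`: summaries `overall`, `adjusted`,
#'   `by_sex`, `by_age_band`, `by_risk_category`, plus `n_complete`
#'   and the per-user `deltas` matrix.
#' @export
masking_experiment <- function(cohort, models = default_models(),
                               ref_policy = reference_policy(),
                               cap = cap_policy(),
                               risk_breaks = c(0.10, 0.20),
                               adjust = c("age", "sex", "country")) {
  stopifnot(is.data.frame(cohort))
  cohort <- validate_questionnaire(cohort)
  complete <- !is.na(cohort$tc) & !is.na(cohort$hdl) &
    !is.na(cohort$sbp) & !is.na(cohort$bmi)
  sub <- cohort[complete, , drop = FALSE]
  if (!nrow(sub))
    stop_heartage("complete subsample is empty", "heartage_empty_report")

  ha <- vapply(ALGORITHM_IDS, function(a) {
    masked <- sub
    keep <- ALGORITHM_MEASURES[[a]]
    for (m in setdiff(c("tc", "hdl", "sbp", "bmi"), keep))
      masked[[m]] <- NA_real_
    score_cohort(masked, models, ref_policy, cap,
                 algorithm = a)$heart_age
  }, numeric(nrow(sub)))
  if (!is.matrix(ha))
    ha <- matrix(ha, nrow = nrow(sub),
                 dimnames = list(NULL, ALGORITHM_IDS))
  full <- ha[, "FULL"]
  deltas <- ha - full    # relative-HA delta = HA_alt - HA_full
  alts <- setdiff(ALGORITHM_IDS, "FULL")

  summarize <- function(idx) {
    data.frame(
      algorithm = alts,
      n = length(idx),
      mean = colMeans(deltas[idx, alts, drop = FALSE]),
      sd = apply(deltas[idx, alts, drop = FALSE], 2, stats::sd),
      row.names = NULL)
  }
  by_group <- function(groups) {
    g <- split(seq_len(nrow(sub)), groups)
    out <- do.call(rbind, lapply(names(g), function(k) {
      s <- summarize(g[[k]]); s$group <- k; s
    }))
    out[, c("group", "algorithm", "n", "mean", "sd")]
  }

  risk_full <- score_cohort(sub, models, ref_policy, cap,
                            algorithm = "FULL")$risk_10y
  risk_cat <- cut(risk_full, breaks = c(0, risk_breaks, 1),
                  labels = c(sprintf("<%.0f%%", 100 * risk_breaks[1]),
                             sprintf("%.0f-%.0f%%", 100 * risk_breaks[1],
                                     100 * risk_breaks[2]),
                             sprintf(">%.0f%%", 100 * risk_breaks[2])),
                  include.lowest = TRUE)
  age_band <- cut(sub$age, breaks = c(seq(20, 70, 10), 80),
                  labels = c("21-30", "31-40", "41-50", "51-60",
                             "61-70", "71-80"), include.lowest = TRUE)

  adjust <- intersect(adjust, names(sub))
  covars <- sub[, adjust, drop = FALSE]
  long <- data.frame(
    delta = as.vector(deltas[, alts]),
    algorithm = rep(alts, each = nrow(sub)))
  covars_long <- covars[rep(seq_len(nrow(sub)), length(alts)), ,
                        drop = FALSE]
  adj <- adjusted_means(long$delta, long$algorithm,
                        as.list(covars_long))
  names(adj)[1] <- "algorithm"

  structure(
    list(overall = summarize(seq_len(nrow(sub))),
         adjusted = adj,
         by_sex = by_group(sub$sex),
         by_age_band = by_group(age_band),
         by_risk_category = by_group(risk_cat),
         n_complete = nrow(sub),
         deltas = deltas),
    class = "masking_report")
}

#' @export
print.masking_report <- function(x, ...) {
  cat(sprintf(
    "Algorithm-masking experiment (complete subsample, n = %d)\n",
    x$n_complete))
  cat("Relative Heart Age delta vs full algorithm (years):\n")
  ov <- merge(x$overall, x$adjusted, by = "algorithm")
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  %-16s mean %+5.2f (SD %4.2f)  adjusted %+5.2f (SE %.3f)\n",
                ov$algorithm[i], ov$mean[i], ov$sd[i],
                ov$adjusted_mean[i], ov$se[i]))
  invisible(x)
}

#' @export
summary.masking_report <- function(object, ...) {
  print(object)
  cat("\nBy sex:\n"); print(object$by_sex, digits = 3)
  cat("\nBy age band:\n"); print(object$by_age_band, digits = 3)
  cat("\nBy 10-year CVD risk category:\n")
  print(object$by_risk_category, digits = 3)
  invisible(object)
}

#' @export
plot.masking_report <- function(x, ...) {
  graphics::barplot(stats::setNames(x$adjusted$adjusted_mean,
                                    x$adjusted$algorithm),
                    ylab = "adjusted mean relative-Heart-Age delta (yr)",
                    las = 2, ...)
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`, where `L0` and `L1` are
#' the likelihoods of the null (intercept-only, or supplied reference)
#' and fitted models.
#'
#' @param fit a fitted binomial [stats::glm] model.
#' @param null optional reference model (default: intercept-only on
#'   the same data).
#' @return A value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null = NULL) {
  n <- stats::nobs(fit)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- if (!is.null(null)) {
    as.numeric(stats::logLik(null))
  } else {
    # intercept-only Bernoulli log-likelihood in closed form
    y <- fit$y
    p <- mean(y)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

#' Awareness logistic regression for one characteristic
#'
#' Fits a logistic regression of the awareness indicator for one
#' physiological measure on a single characteristic plus an adjustment
#' set (by default age, sex and country), and reports the
#' characteristic's odds ratio with a Wald 95% CI together with the
#' Nagelkerke R-squared uniquely attributable to the characteristic —
#' the difference between the full model's R-squared and that of the
#' adjusters-only model.  Non-convergence or separation is flagged on
#' the result rather than raised.
#'
#' @param cohort validated cohort with `aware_tc`/`aware_hdl`/
#'   `aware_sbp` columns.
#' @param outcome which awareness indicator: `"tc"`, `"hdl"`, `"sbp"`.
#' @param characteristic column name of the predictor of interest.
#' @param adjusters adjustment-set column names (those absent from the
#'   cohort are dropped; the characteristic itself is excluded).
#' @param level confidence level.
#' @return An `awareness_fit` with `or`, `ci`, `r2_increment`,
#'   `coefficient`, `se`, `converged`, `flagged` and the underlying
#'   `fit`.
#' @export
awareness_regression <- function(cohort, outcome = c("tc", "hdl", "sbp"),
                                 characteristic,
                                 adjusters = c("age", "sex", "country"),
                                 level = 0.95) {
  outcome <- match.arg(outcome)
  ycol <- paste0("aware_", outcome)
  if (is.null(cohort[[ycol]]))
    stop_heartage(sprintf("cohort lacks %s", ycol),
                  "heartage_input_error")
  if (is.null(cohort[[characteristic]]))
    stop_heartage(sprintf("cohort lacks characteristic '%s'",
                          characteristic),
                  "heartage_input_error")
  adjusters <- setdiff(intersect(adjusters, names(cohort)),
                       characteristic)
  rhs0 <- if (length(adjusters))
    paste(adjusters, collapse = " + ") else "1"
  dat <- cohort[, unique(c(ycol, characteristic, adjusters)),
                drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  f1 <- stats::as.formula(paste(ycol, "~", characteristic, "+", rhs0))
  f0 <- stats::as.formula(paste(ycol, "~", rhs0))
  ctrl <- stats::glm.control(epsilon = 1e-12)
  fit <- stats::glm(f1, family = stats::binomial(), data = dat,
                    control = ctrl)
  fit0 <- stats::glm(f0, family = stats::binomial(), data = dat,
                     control = ctrl)
  cf <- summary(fit)$coefficients
  # first coefficient row belonging to the characteristic
  row <- grep(paste0("^", characteristic), rownames(cf))[1]
  est <- cf[row, 1]; se <- cf[row, 2]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  flagged <- !fit$converged || se > 100   # separation blows up the SE
  structure(
    list(outcome = outcome, characteristic = characteristic,
         term = rownames(cf)[row],
         coefficient = est, se = se,
         or = exp(est), ci = exp(est + c(-1, 1) * zq * se),
         r2_increment = nagelkerke_r2(fit) - nagelkerke_r2(fit0),
         level = level, n = stats::nobs(fit),
         converged = fit$converged, flagged = flagged, fit = fit),
    class = "awareness_fit")
}

#' @export
print.awareness_fit <- function(x, ...) {
  cat(sprintf("Awareness of %s ~ %s (n = %d)\n", toupper(x$outcome),
              x$characteristic, x$n))
  cat(sprintf("  OR %.3f (%.0f%% CI %.3f-%.3f), Nagelkerke R2 increment %.4f%s\n",
              x$or, 100 * x$level, x$ci[1], x$ci[2], x$r2_increment,
              if (x$flagged) "  [flagged: separation/non-convergence]"
              else ""))
  invisible(x)
}
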