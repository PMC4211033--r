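# Intake: unit conversion, validity screening, classification.

test_that("unit conversions use the exact constants and invert cleanly", {
  raw <- data.frame(tc = 5.0, hdl = 1.2, height = 70, weight = 154)
  out <- convert_units(raw, tc_units = "mmoll", height_units = "inch",
                       weight_units = "lb")
  expect_equal(out$tc, 193.35)
  expect_equal(out$hdl, 1.2 * 38.67)
  expect_equal(out$height, 177.8)
  expect_equal(out$weight, 154 * 0.45359237)
  # canonical input is untouched
  iden <- convert_units(data.frame(tc = 180, height = 170, weight = 70))
  expect_identical(iden$tc, 180)
  # conversion then inverse conversion recovers the input
  expect_equal(out$tc / 38.67, 5.0, tolerance = 1e-9)
  expect_equal(out$height / 2.54, 70, tolerance = 1e-9)
  expect_error(convert_units(data.frame(tc = 5, tc_units = "mg")),
               class = "heartage_input_error")
})

test_that("per-row unit tags override the file default", {
  raw <- data.frame(tc = c(5.0, 193.35),
                    tc_units = c("mmoll", "mgdl"))
  out <- convert_units(raw)
  expect_equal(out$tc, c(193.35, 193.35))
  expect_identical(out$tc_units, c("mgdl", "mgdl"))
})

test_that("BMI derivation is exact and rejects non-positive inputs", {
  expect_equal(derive_bmi(180, 81), 25.0)
  expect_equal(derive_bmi(160, 38.4), 15.0)
  expect_error(derive_bmi(170, 0), class = "heartage_input_error")
  expect_error(derive_bmi(-1, 70), class = "heartage_input_error")
})

test_that("out-of-range values become missing, not rejected", {
  raw <- data.frame(age = 50, sex = "male", height = 180, weight = 81,
                    tc = 500, hdl = 50, sbp = 230,
                    aware_tc = TRUE, aware_hdl = TRUE, aware_sbp = TRUE)
  v <- validate_questionnaire(raw)
  expect_true(is.na(v$tc))
  expect_true(is.na(v$sbp))
  expect_equal(v$hdl, 50)
  expect_equal(v$bmi, 25.0)
  expect_false(v$uncomputable)   # HDL and BMI remain usable
  # idempotent
  expect_identical(validate_questionnaire(v), v)
})

test_that("every validity-range endpoint is inclusive-valid", {
  endpoints <- list(tc = c(77, 423), hdl = c(25, 90), sbp = c(80, 220))
  for (m in names(endpoints)) {
    for (val in endpoints[[m]]) {
      raw <- data.frame(age = 50, sex = "male", bmi = 25)
      raw[[m]] <- val
      expect_equal(validate_questionnaire(raw)[[m]], val,
                   info = paste(m, val))
      # one unit beyond either endpoint is missing
      raw[[m]] <- val + if (val == endpoints[[m]][1]) -1 else 1
      expect_true(is.na(validate_questionnaire(raw)[[m]]),
                  info = paste(m, "beyond", val))
    }
  }
  # BMI endpoints via height/weight
  for (b in c(15, 45)) {
    raw <- data.frame(age = 50, sex = "male", height = 160,
                      weight = b * 1.6^2)
    expect_equal(validate_questionnaire(raw)$bmi, b)
  }
})

test_that("the awareness gate blanks values the user cannot know", {
  raw <- data.frame(age = 50, sex = "male", bmi = 25,
                    tc = 200, hdl = 50, sbp = 130,
                    aware_tc = FALSE, aware_hdl = FALSE,
                    aware_sbp = TRUE)
  v <- validate_questionnaire(raw)
  expect_true(is.na(v$tc) && is.na(v$hdl))
  expect_equal(v$sbp, 130)
})

test_that("a record with no usable physiological value is uncomputable", {
  raw <- data.frame(age = 50, sex = "male", height = 170, weight = 150,
                    tc = NA, hdl = NA, sbp = NA)
  expect_true(validate_questionnaire(raw)$uncomputable)
})

test_that("classification thresholds follow the printed inequalities", {
  mk <- function(...) {
    d <- data.frame(age = 50, sex = "male", smoker = FALSE,
                    diabetic = FALSE, family_history = FALSE,
                    tc = NA_real_, hdl = NA_real_, sbp = NA_real_,
                    bmi = NA_real_)
    args <- list(...)
    for (nm in names(args)) d[[nm]] <- args[[nm]]
    classify_risk_factors(d)
  }
  # boundary battery: >= for high TC/SBP/BMI, <= for low HDL
  expect_true(mk(tc = 240)$high_tc);  expect_false(mk(tc = 239)$high_tc)
  expect_true(mk(hdl = 40)$low_hdl);  expect_false(mk(hdl = 41)$low_hdl)
  expect_true(mk(sbp = 140)$high_sbp); expect_false(mk(sbp = 139)$high_sbp)
  expect_true(mk(bmi = 25)$overweight); expect_false(mk(bmi = 24.9)$overweight)
  expect_true(mk(bmi = 30)$obese);    expect_false(mk(bmi = 29.9)$obese)
})

test_that("unhealthy-factor count follows the documented membership", {
  ref <- data.frame(age = 55, sex = "male", smoker = FALSE,
                    diabetic = FALSE, family_history = FALSE,
                    tc = 180, hdl = 45, sbp = 125, bmi = 22.5)
  expect_equal(classify_risk_factors(ref)$unhealthy_count, 0L)

  mixed <- data.frame(age = 55, sex = "male", smoker = TRUE,
                      diabetic = FALSE, family_history = FALSE,
                      tc = 180, hdl = NA_real_, sbp = 150, bmi = 31)
  cl <- classify_risk_factors(mixed)
  expect_true(cl$current_smoker && cl$overweight && cl$obese &&
                cl$high_sbp)
  # obesity is subsumed by overweight; missing HDL contributes nothing
  expect_equal(cl$unhealthy_count, 3L)
  expect_true(is.na(cl$low_hdl))   # missing flag is NA, never FALSE
})

test_that("questionnaire CSV round-trips through read/write", {
  coh <- generate_cohort(cohort_config(n = 50, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_questionnaire(coh, f)
  back <- read_questionnaire(f)
  expect_equal(back$age, coh$age)
  expect_equal(back$tc, coh$tc)
  expect_equal(back$smoker, coh$smoker)
  expect_identical(back$usage_date, coh$usage_date)
})
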