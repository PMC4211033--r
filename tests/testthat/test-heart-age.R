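# Heart Age: reference profiles, inversion, capping, full pipeline.

test_that("reference profiles carry the documented normal values", {
  p <- reference_profile(55, "male", "FULL")
  expect_equal(p$tc, 180)
  expect_equal(p$hdl, 45)
  expect_equal(p$sbp, 125)
  expect_false(p$smoker); expect_false(p$diabetic)
  expect_false(p$bp_treated)
  expect_true(is.na(p$bmi))   # FULL does not use BMI

  # reference SBP steps to 130 at age 60
  expect_equal(reference_profile(60, "male", "FULL")$sbp, 130)
  expect_equal(reference_profile(59, "male", "FULL")$sbp, 125)

  # models with TC but no HDL use the raised 200 mg/dl reference
  p2 <- reference_profile(50, "female", "ALT2_TC_SBP_BMI")
  expect_equal(p2$tc, 200)
  expect_equal(p2$sbp, 125)
  expect_equal(p2$bmi, 22.5)
  expect_true(is.na(p2$hdl))
  # ...but ALT1, which keeps HDL, stays at 180
  expect_equal(reference_profile(50, "female", "ALT1_TC_HDL")$tc, 180)
})

test_that("inverting 10% risk for a man gives the age-55 anchor", {
  fm <- get_model(default_models(), "FULL", "male")
  ha <- invert_heart_age(0.10, fm)
  expect_equal(ha, 55, tolerance = 0.5 / 55)
  # a 40-year-old with that risk lands exactly on the +15 cap boundary
  expect_equal(floor(cap_heart_age(ha, 40) + 0.5), 55)
})

test_that("inversion round-trips the reference curve", {
  models <- default_models()
  for (sx in c("male", "female")) {
    m <- get_model(models, "FULL", sx)
    r48 <- reference_risk(48, m)
    expect_equal(invert_heart_age(r48, m), 48, tolerance = 0.01 / 48)
  }
})

test_that("bisection matches the 0.01-step grid oracle within 0.01 years", {
  models <- default_models()
  set.seed(314)
  for (sx in c("male", "female")) {
    for (alg in c("FULL", "ALT4_SBP_BMI")) {
      m <- get_model(models, alg, sx)
      lo <- reference_risk(18, m); hi <- reference_risk(80, m)
      risks <- runif(50, lo * 1.01, hi * 0.99)
      got <- invert_heart_age(risks, m)
      want <- oracle_grid_invert(risks, m)
      expect_lt(max(abs(got - want)), 0.01)
    }
  }
  # the spot value from the grid oracle
  fm <- get_model(models, "FULL", "male")
  expect_equal(invert_heart_age(0.05, fm), oracle_grid_invert(0.05, fm),
               tolerance = 0.01 / 45)
})

test_that("inversion is monotone in risk and resolves the age-60 gap", {
  fm <- get_model(default_models(), "FULL", "male")
  grid <- seq(0.01, 0.6, by = 0.005)
  ages <- invert_heart_age(grid, fm)
  expect_true(all(diff(ages) >= 0))
  # risks strictly inside the reference-SBP discontinuity map to 60
  gap <- c(reference_risk(60 - 1e-9, fm), reference_risk(60, fm))
  inside <- gap[1] + diff(gap) * c(0.25, 0.5, 0.75)
  expect_equal(invert_heart_age(inside, fm), rep(60, 3),
               tolerance = 1e-6)
  # out-of-domain risks clamp to the age domain pre-cap
  expect_equal(invert_heart_age(reference_risk(18, fm) / 2, fm), 18)
  expect_equal(invert_heart_age(0.99, fm), 80)
})

test_that("capping clamps to the +/-15 window and the 18-80 range", {
  expect_equal(cap_heart_age(60.4, 40), 55)   # +15 binds
  expect_equal(cap_heart_age(10.0, 25), 18)   # floor binds before age-15
  expect_equal(cap_heart_age(92.0, 72), 80)   # ceiling binds before age+15
  # exhaustive grid: clamp algebra, idempotence, bounds
  grid <- expand.grid(uncapped = seq(5, 95, by = 2.5),
                      age = 21:80)
  capped <- cap_heart_age(grid$uncapped, grid$age)
  expect_true(all(capped >= 18 & capped <= 80))
  expect_true(all(abs(capped - grid$age) <= 15))
  expect_equal(cap_heart_age(capped, grid$age), capped)
  # order-insensitive: clamping by the two bound pairs in either order
  lo1 <- pmax(pmin(grid$uncapped, grid$age + 15), grid$age - 15)
  both <- pmin(pmax(lo1, 18), 80)
  alt <- pmax(pmin(pmin(pmax(grid$uncapped, 18), 80), grid$age + 15),
              grid$age - 15)
  keep <- both == alt   # orders agree except where bounds conflict
  expect_equal(capped[keep], both[keep])
})

test_that("the full pipeline reproduces the 40-year-old example", {
  models <- default_models()
  fm <- get_model(models, "FULL", "male")
  # engineer a 40-year-old male profile whose 10-year risk is exactly 10%
  tc10 <- uniroot(function(tc) {
    ten_year_risk(risk_profile(40, "male", smoker = TRUE, tc = tc,
                               hdl = 38, sbp = 150), fm) - 0.10
  }, c(100, 423), tol = 1e-12)$root
  res <- heart_age(risk_profile(40, "male", smoker = TRUE, tc = tc10,
                                hdl = 38, sbp = 150))
  expect_equal(res$risk_10y, 0.10, tolerance = 1e-9)
  expect_identical(res$algorithm, "FULL")
  expect_equal(res$heart_age_display, 55)
  expect_equal(round(res$relative_heart_age), 15)
  expect_false(res$capped)
})

test_that("a reference-normal user gets their own age back", {
  for (age in c(25, 40, 55, 70)) {
    for (sx in c("male", "female")) {
      p <- reference_profile(age, sx, "FULL")
      res <- heart_age(p)
      expect_equal(res$heart_age, age, tolerance = 1 / age)
      expect_identical(res$algorithm, "FULL")
    }
  }
})

test_that("heart_age respects the cap policy for extreme profiles", {
  res <- heart_age(risk_profile(25, "male", smoker = TRUE,
                                diabetic = TRUE, tc = 320, hdl = 28,
                                sbp = 200, bp_treated = TRUE))
  expect_lte(res$heart_age, 40)           # 25 + 15
  expect_true(res$capped)
  res2 <- heart_age(risk_profile(78, "female", tc = 130, hdl = 88,
                                 sbp = 95))
  expect_gte(res2$heart_age, 63)          # 78 - 15
  expect_lte(res2$heart_age, 80)
})

test_that("algorithm selection feeds the pipeline (HDL w/o TC ignored)", {
  res <- heart_age(risk_profile(50, "female", hdl = 50, sbp = 120,
                                bmi = 24))
  expect_identical(res$algorithm, "ALT4_SBP_BMI")
  expect_error(heart_age(risk_profile(50, "female", tc = 200)),
               class = "heartage_uncomputable")
})
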