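# Risk-equation engine: coefficient loading, linear predictor, risk.

test_that("bundled coefficient file yields 12 validated models", {
  models <- default_models()
  expect_s3_class(models, "risk_model_set")
  expect_length(models, 12L)
  expect_match(attr(models, "version"), "heartage-coefficients")

  fm <- get_model(models, "FULL", "male")
  expect_setequal(required_inputs(fm),
                  c("age", "tc", "hdl", "sbp", "smoker", "diabetic",
                    "bp_treated"))
  # treated and untreated SBP variants both present
  sbp_terms <- fm$terms[fm$terms$name == "sbp", ]
  expect_setequal(sbp_terms$treated, c(TRUE, FALSE))
  # BMI-only model consumes no lipids or blood pressure
  a5 <- get_model(models, "ALT5_BMI", "female")
  expect_setequal(required_inputs(a5),
                  c("age", "bmi", "smoker", "diabetic"))
})

test_that("configuration errors name the offending entry", {
  doc <- yaml::read_yaml(system.file("extdata",
                                     "heartage-coefficients.yaml",
                                     package = "heartage"))
  bad <- doc
  bad$models[[1]]$baseline_survival_10y <- 1.2
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(load_models(f), "FULL/male.*outside",
               class = "heartage_config_error")

  bad2 <- doc
  bad2$models[[3]]$terms[[1]]$coefficient <- NaN
  yaml::write_yaml(bad2, f)
  expect_error(load_models(f), "non-finite",
               class = "heartage_config_error")

  bad3 <- doc
  bad3$models[[5]] <- NULL
  yaml::write_yaml(bad3, f)
  expect_error(load_models(f), "missing entries",
               class = "heartage_config_error")
})

test_that("coefficient file round-trips exactly", {
  m1 <- default_models()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_models(m1, f)
  m2 <- load_models(f)
  expect_equal(m1, m2, tolerance = 0)
})

test_that("linear predictor matches independent term-by-term evaluation", {
  fm <- get_model(default_models(), "FULL", "male")
  p <- risk_profile(55, "male", tc = 180, hdl = 45, sbp = 125)
  # hand evaluation with the published coefficients
  expected <- 3.06117 * log(55) + 1.12370 * log(180) -
    0.93263 * log(45) + 1.93303 * log(125)
  expect_equal(linear_predictor(p, fm), expected, tolerance = 1e-12)

  # one indicator term: smoking adds exactly its coefficient
  ps <- risk_profile(55, "male", smoker = TRUE, tc = 180, hdl = 45,
                     sbp = 125)
  expect_equal(linear_predictor(ps, fm) - linear_predictor(p, fm),
               0.65451, tolerance = 1e-12)

  # treated blood pressure switches the SBP coefficient
  pt <- risk_profile(55, "male", tc = 180, hdl = 45, sbp = 125,
                     bp_treated = TRUE)
  expect_equal(linear_predictor(pt, fm) - linear_predictor(p, fm),
               (1.99881 - 1.93303) * log(125), tolerance = 1e-12)
})

test_that("risk collapses to 1 - S0 when LP equals the cohort mean", {
  for (key in c("FULL.male", "ALT1_TC_HDL.female", "ALT5_BMI.male")) {
    m <- default_models()[[key]]
    # rescale the age value so the linear predictor hits mean_lp exactly
    p <- data.frame(age = 50, tc = 200, hdl = 50, sbp = 120, bmi = 25,
                    smoker = 0, diabetic = 0, bp_treated = FALSE)
    lp0 <- heartage:::eval_lp(m, p)
    b_age <- m$terms$coefficient[m$terms$name == "age"]
    p$age <- exp(log(50) + (m$mean_lp - lp0) / b_age)
    expect_equal(heartage:::eval_lp(m, p), m$mean_lp, tolerance = 1e-9)
    expect_equal(heartage:::risk_from_lp(heartage:::eval_lp(m, p), m),
                 1 - m$s0_10, tolerance = 1e-9)
  }
})

test_that("missing and non-positive inputs raise informative errors", {
  fm <- get_model(default_models(), "FULL", "male")
  p <- risk_profile(55, "male", tc = 180, hdl = NA, sbp = 125)
  expect_error(linear_predictor(p, fm), "hdl",
               class = "heartage_missing_input")
  bad <- data.frame(age = 50, tc = -1, hdl = 45, sbp = 120,
                    smoker = 0, diabetic = 0, bp_treated = FALSE)
  expect_error(heartage:::eval_lp(fm, bad), "non-positive",
               class = "heartage_domain_error")
})

test_that("risk evaluation matches the brute-force oracle to 1e-12", {
  doc <- oracle_models()
  models <- default_models()
  prof <- random_profiles(100)
  for (alg in c("FULL", "ALT1_TC_HDL", "ALT2_TC_SBP_BMI",
                "ALT3_TC_BMI", "ALT4_SBP_BMI", "ALT5_BMI")) {
    for (i in seq_len(nrow(prof))) {
      row <- as.list(prof[i, ])
      m <- get_model(models, alg, row$sex)
      p <- risk_profile(row$age, row$sex, smoker = row$smoker,
                        diabetic = row$diabetic, tc = row$tc,
                        hdl = row$hdl, sbp = row$sbp,
                        bp_treated = row$bp_treated, bmi = row$bmi)
      expected <- oracle_risk(row, oracle_entry(doc, alg, row$sex))
      expect_equal(ten_year_risk(p, m), expected, tolerance = 1e-12)
    }
  }
})

test_that("risk is bounded, monotone in age, and signs follow the terms", {
  models <- default_models()
  base <- data.frame(age = 50, tc = 200, hdl = 50, sbp = 130, bmi = 26,
                     smoker = 0, diabetic = 0, bp_treated = FALSE)
  for (m in models) {
    # bounded on random profiles
    prof <- random_profiles(50, seed = 7)
    prof$smoker <- as.numeric(prof$smoker)
    prof$diabetic <- as.numeric(prof$diabetic)
    r <- heartage:::risk_from_lp(heartage:::eval_lp(m, prof), m)
    expect_true(all(r > 0 & r < 1))
    # strictly increasing in age with all else fixed
    grid <- base[rep(1, 63), ]; grid$age <- 18:80
    rr <- heartage:::risk_from_lp(heartage:::eval_lp(m, grid), m)
    expect_true(all(diff(rr) > 0))
    # sign contract per covariate present in the model
    bump <- function(col, delta) {
      d <- base; d[[col]] <- d[[col]] + delta
      heartage:::risk_from_lp(heartage:::eval_lp(m, d), m) -
        heartage:::risk_from_lp(heartage:::eval_lp(m, base), m)
    }
    terms <- unique(m$terms$name)
    if ("tc" %in% terms) expect_gt(bump("tc", 20), 0)
    if ("hdl" %in% terms) expect_lt(bump("hdl", 10), 0)
    if ("sbp" %in% terms) expect_gt(bump("sbp", 10), 0)
    if ("bmi" %in% terms) expect_gt(bump("bmi", 3), 0)
    expect_gt(bump("smoker", 1), 0)
    expect_gt(bump("diabetic", 1), 0)
  }
})

test_that("algorithm selection covers all 16 availability patterns", {
  expected <- list(
    # tc, hdl, sbp, bmi -> algorithm (NA = uncomputable)
    list(c(T, T, T, T), "FULL"), list(c(T, T, T, F), "FULL"),
    list(c(T, T, F, T), "ALT1_TC_HDL"), list(c(T, T, F, F), "ALT1_TC_HDL"),
    list(c(T, F, T, T), "ALT2_TC_SBP_BMI"), list(c(T, F, T, F), NA),
    list(c(T, F, F, T), "ALT3_TC_BMI"), list(c(T, F, F, F), NA),
    list(c(F, T, T, T), "ALT4_SBP_BMI"), list(c(F, T, T, F), NA),
    list(c(F, T, F, T), "ALT5_BMI"), list(c(F, T, F, F), NA),
    list(c(F, F, T, T), "ALT4_SBP_BMI"), list(c(F, F, T, F), NA),
    list(c(F, F, F, T), "ALT5_BMI"), list(c(F, F, F, F), NA))
  for (case in expected) {
    av <- case[[1]]
    if (is.na(case[[2]])) {
      expect_error(select_algorithm(av[1], av[2], av[3], av[4]),
                   class = "heartage_uncomputable")
    } else {
      expect_identical(select_algorithm(av[1], av[2], av[3], av[4]),
                       case[[2]])
    }
  }
})
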