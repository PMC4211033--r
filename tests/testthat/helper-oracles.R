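# Independent oracles used across the suite.

# Term-by-term risk evaluation straight from the YAML coefficient
# document, sharing no code with the package's evaluator.
oracle_models <- function() {
  path <- system.file("extdata", "heartage-coefficients.yaml",
                      package = "heartage")
  yaml::read_yaml(path)$models
}

oracle_entry <- function(doc, algorithm, sex) {
  for (m in doc) if (m$algorithm == algorithm && m$sex == sex) return(m)
  stop("no such model")
}

# profile: list with age, tc, hdl, sbp, bmi, smoker, diabetic,
# bp_treated.  Returns the 10-year risk by explicit summation.
oracle_risk <- function(profile, entry) {
  lp <- 0
  for (t in entry$terms) {
    x <- profile[[t$name]]
    v <- switch(t$transform, log = log(x), identity = x,
                indicator = as.numeric(x))
    if (!is.null(t$treated))
      v <- v * as.numeric(profile$bp_treated == t$treated)
    lp <- lp + t$coefficient * v
  }
  1 - entry$baseline_survival_10y ^
    exp(lp - entry$mean_linear_predictor)
}

# Brute-force inversion: walk the 0.01-year age grid of the
# reference-normal curve and return the age minimizing |risk - r|.
oracle_grid_invert <- function(risk, model,
                               policy = reference_policy()) {
  ages <- seq(18, 80, by = 0.01)
  curve <- reference_risk(ages, model, policy)
  vapply(risk, function(r) ages[which.min(abs(curve - r))], numeric(1))
}

# Random valid profiles drawn inside the validity ranges.
random_profiles <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    age = runif(n, 21, 80),
    sex = sample(c("male", "female"), n, TRUE),
    tc = runif(n, 100, 320),
    hdl = runif(n, 28, 85),
    sbp = runif(n, 90, 200),
    bmi = runif(n, 17, 42),
    smoker = runif(n) < 0.3,
    diabetic = runif(n) < 0.1,
    bp_treated = runif(n) < 0.2)
}

# A small questionnaire fixture with disjoint, labeled defects:
# 83 clean rows, 7 default-age-20 rows, 5 repeat users, 3 rows with
# every physiological value missing or invalid, and 2 exact duplicates
# of clean rows.
cleaning_fixture <- function() {
  set.seed(99)
  n <- 98
  base <- data.frame(
    age = sample(25:70, n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    height = round(runif(n, 155, 190)),
    weight = round(runif(n, 55, 95), 1),
    tc = round(runif(n, 120, 300)),
    hdl = round(runif(n, 30, 80)),
    sbp = round(runif(n, 95, 180)),
    smoker = runif(n) < 0.25, diabetic = runif(n) < 0.05,
    family_history = runif(n) < 0.3,
    bp_treated = FALSE, chol_treated = FALSE,
    aware_tc = TRUE, aware_hdl = TRUE, aware_sbp = TRUE,
    repeat_user = FALSE,
    usage_date = as.character(as.Date("2010-01-01") + seq_len(n)),
    country = "UK")
  base$age[1:7] <- 20                       # default-age rows
  base$repeat_user[8:12] <- TRUE            # repeat users
  base$tc[13:15] <- NA; base$hdl[13:15] <- NA; base$sbp[13:15] <- NA
  # weight chosen so BMI is 50, beyond the validity range
  base$weight[13:15] <- round(50 * (base$height[13:15] / 100)^2, 1)
  dup <- base[16:17, ]                      # exact copies of clean rows
  rbind(base, dup)
}
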