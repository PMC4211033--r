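Package: heartage
Title: Heart Age and 10-Year Cardiovascular Risk with Missing-Data
    Algorithms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes 10-year cardiovascular disease risk from
    sex-specific Framingham-style Cox proportional-hazards risk
    equations and translates it into a "Heart Age" by inverting the
    reference-profile risk curve, with capping to a plausible range.
    A family of six algorithms handles users whose cholesterol, blood
    pressure or body-mass-index values are unknown, selecting the
    richest computable equation from per-field availability.  Includes
    questionnaire intake with unit conversion and validity screening, a
    seeded synthetic-cohort generator with configurable awareness
    structure and data pathologies, a cleaning cascade, an
    algorithm-masking experiment quantifying how unknown risk-factor
    values distort Heart Age, and per-characteristic awareness logistic
    regressions with Nagelkerke R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    survival,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
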