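---
title: "Heart Age from Framingham risk equations: models, policies, and the synthetic-cohort laboratory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart Age methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartage)
```

## The risk model

The package scores 10-year general cardiovascular disease (CVD) risk
with sex-specific Cox proportional-hazards risk functions in the
Framingham style.  For a covariate vector $x$ the risk is

$$ P(\text{CVD within 10 y}) \;=\; 1 - S_0(10)^{\exp(\beta'x - \bar L)}, $$

where $\beta'x$ is the linear predictor over log-transformed
continuous covariates (age, total cholesterol TC, HDL cholesterol,
systolic blood pressure SBP, body-mass index BMI) and indicator terms
(current smoking, diabetes), $\bar L$ is the derivation cohort's mean
linear predictor, and $S_0(10)$ the 10-year baseline survival at
$\bar L$.  Models carrying SBP use separate coefficients for treated
and untreated blood pressure, switched by the antihypertensive
medication flag.  Risk is strictly increasing in age, TC, SBP, BMI,
smoking and diabetes and decreasing in HDL for every bundled model;
the test suite asserts these sign contracts directly.

Because web users often cannot report a cholesterol or blood-pressure
value, the engine carries a family of six equations and selects the
richest one computable from the available fields:

| algorithm | physiological inputs |
|---|---|
| `FULL` | TC, HDL, SBP |
| `ALT1_TC_HDL` | TC, HDL |
| `ALT2_TC_SBP_BMI` | TC, SBP, BMI |
| `ALT3_TC_BMI` | TC, BMI |
| `ALT4_SBP_BMI` | SBP, BMI |
| `ALT5_BMI` | BMI |

All models additionally use age, smoking and diabetes.  An HDL value
without a TC value is ignored (treated as lipids unknown): no
equation consumes HDL alone, and the questionnaire's cholesterol
dialogue collects the two together.  A record offering none of the
four measures is uncomputable and raises a typed error
(`heartage_uncomputable`).

### Coefficient provenance

Coefficients live in a versioned YAML document
(`inst/extdata/heartage-coefficients.yaml`) so an alternative
coefficient source can replace them without code changes; the file's
version string is carried through every report for provenance.  The
`FULL` (lipid-based) and `ALT4` (office-based, BMI + SBP) entries are
the published sex-specific general-CVD equations of the Framingham
Heart Study (D'Agostino et al., *Circulation* 2008), whose covariate
sets match those two algorithms exactly.  No usable published
coefficients exist for the remaining partial covariate sets, so
`ALT1`, `ALT2`, `ALT3` and `ALT5` were refit by maximum partial
likelihood (via `survival::coxph`) on a synthetic Framingham-like
cohort of 400,000 subjects per sex whose event process was generated
from the `FULL` model: ages uniform on 30–74; physiological values
from truncated normals linked by a Gaussian copula with modest
conventional correlations (TC–SBP 0.12, TC–BMI 0.15, SBP–BMI 0.25,
HDL–BMI −0.35, HDL–TC −0.10, HDL–SBP −0.05) and mild age trends;
event times exponential with the baseline calibrated to $S_0(10)$ and
administrative censoring at 10 years.  Each refit equation therefore
marginalizes the full model over the measures it does not observe,
given those covariate correlations.  The refit script
(`tools/refit-partial-models.R`) is deterministic and its output is
frozen into the bundled file; the refit coefficients are a modelling
convention of this package, not published values.

## Heart Age

A user's Heart Age is the age at which a person of the same sex with
all risk factors at reference-"normal" values would have the same
predicted 10-year risk.  The reference values are: non-smoking,
non-diabetic, untreated SBP 125 mmHg (130 mmHg from age 60), TC
180 mg/dl and HDL 45 mg/dl; for equations that use TC without HDL the
reference TC is raised to 200 mg/dl, which increases their
sensitivity.  The reference BMI is not defined by the risk equations'
source; the package uses 22.5 kg/m² — the midpoint of the
conventional normal band — exposed as a configurable
`reference_policy()` field and flagged here as this package's choice.

`invert_heart_age()` solves $\text{risk}_{\text{ref}}(a) = r$ by
bisection on $a \in [18, 80]$.  Numerical choices:

* 52 fixed halvings of the 62-year bracket put the final bracket
  width below $2^{-45}$ years; wherever the curve is continuous the
  achieved $|\Delta \text{risk}|$ is far below $10^{-10}$.
* The reference SBP step makes the reference curve discontinuous at
  age 60 for SBP-bearing models.  A risk falling inside the gap has
  no exact preimage; bisection converges to the jump point and the
  result is 60 exactly — a deterministic, monotone-preserving
  tie-break.
* A risk below the reference risk at 18 (or above at 80) returns 18
  (80) pre-cap; the cap policy finishes the clamping.

Capping (`cap_policy()`) clamps Heart Age to
$[\max(18, a-15), \min(80, a+15)]$ for chronological age $a$; the
operation is idempotent and order-insensitive except in the
degenerate corner where the two bound pairs conflict, which the
domain ($a \in [21, 80]$) excludes.  Heart Age stays real-valued
internally; presentation rounds half-up to integer years *after*
capping, so a capped 54.5 displays as 55 while the `capped` flag
compares rounded uncapped and capped values.

Self-consistency is the key invariant: for every age 21–80, both
sexes and all six algorithms, the reference profile's own risk
inverts back to that age within 0.01 years pre-cap (outside a
±1-year neighborhood of the age-60 step).  The suite verifies this
exhaustively, plus agreement with a brute-force 0.01-year grid-search
inversion oracle.

## Intake

Canonical units are cm, kg, mg/dl and mmHg.  Cholesterol in mmol/l is
converted at 38.67 mg/dl per mmol/l (from the molar mass of
cholesterol; the questionnaire specifies units per locale but no
constant), height at 2.54 cm/inch, weight at 0.45359237 kg/lb.
Validity screening treats out-of-range values as *missing*, never as
errors: SBP 80–220 mmHg, TC 77–423 mg/dl, HDL 25–90 mg/dl, BMI
15–45 kg/m², endpoints inclusive.  A "Do you know your …?" awareness
flag of `FALSE` blanks the corresponding value even if a batch CSV
carries one (the interactive dialogue makes that state unreachable;
files can contain it).

Classification uses TC ≥ 240 (high), HDL ≤ 40 (low), SBP ≥ 140
(high), BMI ≥ 25 (overweight) and ≥ 30 (obese).  The unhealthy-factor
count's membership is not externally defined; the package counts
{smoking, overweight, diabetes, high TC, low HDL, high SBP, family
history}, excluding obesity as subsumed by overweight, and the set is
configurable.  Flags on missing measurements are `NA` — absent, not
false — and contribute nothing to the count.

## The synthetic-cohort generator

`generate_cohort()` emulates the user base of a web-based Heart Age
self-assessment campaign; it is the laboratory in which the package's
analyses run, not a reproduction of any real database.  Its defaults
are fixed study conditions:

* 56.03% female; ages piecewise-uniform within decades with weights
  0.2276 / 0.2139 / 0.2399 / 0.18 / 0.1092 / 0.0294 for the 20s
  through 70s — bimodal with peaks in the 20s and 40s and a sharp
  post-60 decline.  The 30s/50s weights interpolate the remainder and
  are approximate by construction.
* Per-sex truncated-normal physiological values (e.g. TC mean 193.5
  SD 44.0 for men, 197.7/46.6 for women; SBP 127.1/13.3 and
  122.4/14.6) linked by the same kind of Gaussian copula as the refit
  cohort (TC–SBP 0.15, TC–BMI 0.15, SBP–BMI 0.25, HDL–BMI −0.30);
  only marginals are externally sourced, so every correlation setting
  is a convention of this package.
* Prevalences: smoking 23.37%, diabetes 3.39%, family history
  32.84%; antihypertensive 10% and lipid-lowering 8% medication use
  (the latter two are package conventions).
* Awareness of TC, HDL and SBP follows per-measure logistic models
  whose slopes are logs of published per-characteristic odds ratios
  (per year of age 1.07/1.06/1.05; diabetes 1.74/1.48/1.47; smoking
  0.67/0.52/0.71; family history 1.43/1.26/1.22) and whose intercepts
  were calibrated once, against the default covariate mixture, to hit
  marginal awareness of 22.53% (TC), 6.97% (HDL) and 53.45% (SBP).
  HDL awareness is modelled conditionally on TC awareness — users
  effectively never know HDL alone — so the HDL equation's intercept
  targets the marginal via the conditional rate among the TC-aware.
* Labeled pathologies at configurable rates (defaults mirror the
  exclusion fractions such cleaning cascades encounter: 9.59%
  default-age-20, 4.26% repeat users, 0.97% all-invalid, 3.87%
  duplicates).

Generation is bit-reproducible given `(config, seed)`; the `.truth_*`
columns (pre-blanking values, awareness linear predictors, pathology
labels) exist for generator validation only and never feed scoring.

What the generator does **not** emulate: country-specific
composition beyond a categorical site label, calendar-time usage
patterns, reporting error (values are rounded truth, not misrecalled
measurements), and any realistic joint distribution beyond the
configured copula.  Consequently, passing the masking-experiment
checks demonstrates that the *mechanism* — healthy reference values
plus marginalizing partial models — produces systematic Heart Age
overestimation with the expected ordering, not that the simulated
magnitudes equal those any real user base would show.

## The analysis pipeline

`clean_cohort()` applies a fixed-order exclusion cascade — age-20
default rows, ages outside 21–80, repeat users, records with no
usable physiological value, then exact duplicates on (usage date,
BMI, TC, HDL, SBP, Heart Age, 10-year risk) keeping the first — and
itemizes counts per rule; each row is counted under the first rule
that removes it, so counts plus retained rows always equal input
rows, and cleaning is idempotent.

`masking_experiment()` restricts to the complete subsample (valid TC,
HDL, SBP and BMI), recomputes Heart Age under each algorithm by
masking exactly the inputs it ignores, and summarizes the deltas in
relative Heart Age (alternative minus full) overall and by sex,
10-year age band and 10-year CVD risk category.  The risk category
cut points are not externally fixed; the default bins <10%, 10–20%,
>20% are configurable.  Covariate-adjusted means come from a linear
model with centered covariate design columns (age, sex, and site
label when present), whose stratum coefficients are predictions at
the overall covariate means — an adjusted-means simplification that
reports the quantity of interest without repeated-measures
covariance machinery or omnibus F-tests, which are out of scope.

`awareness_regression()` fits one logistic model per characteristic
with an adjustment set (default age, sex, site), reporting the Wald
odds ratio and CI and the Nagelkerke $R^2$ uniquely attributable to
the characteristic,

$$ R^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}, $$

computed as the increment of the full over the adjusters-only model.
Separation or non-convergence flags the result instead of raising.

## Problem sizes and tolerances in the checks

The test suite uses cohorts of 10,000–50,000 for marginal and masking
checks (the complete subsample is then roughly 5% of cleaned rows,
~2,000 users) and twenty replicates of 200,000 for odds-ratio
recovery, sizes at which the measured quantities are stable but the
whole suite runs in well under a minute for the deterministic parts.
Risk evaluation must match an independent term-by-term oracle to
1e-12 relative; inversion must match the 0.01-year grid oracle to
0.01 years; OR recovery requires ≥90% CI coverage across
(replicate × coefficient) checks.

## Known limitations

* The refit partial models inherit every assumption of their
  generating cohort; with different covariate correlations the
  masking deltas would shift.  They are fit-for-purpose stand-ins,
  not published equations.
* The awareness model conditions only on age, diabetes, smoking and
  family history; real awareness also tracks risk level, weight
  status and cross-measure knowledge, which the package's regressions
  can estimate but the generator does not plant.
* The capping policy makes high-risk Heart Ages insensitive to inputs
  (they pin at age + 15), which attenuates masking deltas in the top
  risk category — an intended property of the tool, visible in the
  stratified reports.
* `reference_policy()` and the risk-category bins are conventions
  where the tool's own choices are not externally fixed; both are
  configurable and recorded in every report.

## References

D'Agostino RB, Vasan RS, Pencina MJ, et al.  General cardiovascular
risk profile for use in primary care: the Framingham Heart Study.
*Circulation* 2008;117(6):743–53.
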