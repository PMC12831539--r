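---
title: "Practice-effect change scores and cognitive prognosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Practice-effect change scores and cognitive prognosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(practicefx)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable constants and why they have
the defaults they do, what the synthetic cohort generator does and does
not emulate, and the decisions taken where reasonable alternatives
existed.

## 1. The scientific question

Repeat administration of a cognitive test usually improves the score even
without any change in the underlying ability — the *practice effect*. In
neurodegenerative disease, an attenuated practice effect can be an early
marker: a brain that extracts less benefit from prior exposure may
already be losing plasticity before conventional cross-sectional testing
shows impairment. The analysis implemented here asks two questions about
Parkinson's disease (PD): (i) do PD patients show smaller one-year
practice effects than healthy controls (HC), and (ii) within PD, do
smaller practice effects predict progression to cognitive impairment (CI)
and to a dementia-range screen result (PDD)?

## 2. SRB change scores

For each test in a nine-test battery, a normative prediction equation is
fitted on HC subjects only, by ordinary least squares with an intercept:

$$\hat y_1 = \beta_0 + \beta_1 y_0 + \beta_2\,\mathrm{age}
           + \beta_3\,\mathrm{sex} + \beta_4\,\mathrm{education}
           + \beta_5\,\mathrm{interval}$$

with $y_0$ the baseline score, age in years, sex coded 0 = female /
1 = male, education in years, and the retest interval in months. A
subject's standardized regression-based (SRB) z-score is

$$z = \frac{y_1^{\mathrm{obs}} - \hat y_1}{\hat\sigma_\varepsilon},
\qquad
\hat\sigma_\varepsilon = \sqrt{\mathrm{RSS}/(n-6)} .$$

Assumptions are those of the linear model: an approximately linear
baseline–follow-up relation with additive demographic effects and
homoscedastic residuals. The fit is complete-case *per test*: a subject
missing one test still contributes to every other test's norm, which
matters because battery coverage is very uneven (in the emulated cohort
two tests are available for only ~14% of subjects).

Numerical choices:

* **Residual-SD denominator.** $n-6$ (the unbiased OLS estimator with
  six fitted parameters). With this convention the in-sample HC z-scores
  have mean exactly 0 and sample SD exactly
  $\sqrt{(n-6)/(n-1)}$ — identities the test suite asserts at
  `1e-10`.
* **Minimum normative sample.** Eight complete rows (two more than the
  parameter count); smaller samples raise an error rather than fit.
* **Degenerate fits.** If the follow-up score is an exact linear
  function of the predictors the residual SD is zero and a z-score would
  be undefined; this is reported as an error carrying the fitted
  intercept and baseline slope.
* **Orientation.** The two Trail Making tests are timed, so *lower* is
  better; their z-scores are negated so that across the battery positive
  z always means a larger-than-expected practice effect. Orientation is
  an involution: applying it twice returns the raw score.
* **Trichotomization boundary.** The 5% tails of the standard normal
  give cut points at ±1.645. The package uses the closed convention
  decline iff $z \le -1.645$, improvement iff $z \ge 1.645$, which
  partitions the whole line symmetrically; the cut point is a documented,
  configurable constant.
* **Composite.** The arithmetic mean of the oriented z-scores of six
  designated tests (LNST, SDMT, SFT, JoLO, HVLT-R immediate and
  delayed); BNT and the TMT pair never contribute. How partial batteries
  should be handled is genuinely open; the package requires at least
  `min_tests = 4` of the six members and returns a missing composite
  below that. Four keeps most of the composite's content while not
  discarding subjects who miss one short test.
* **Serialization.** Normative equations are the reusable artifact, so
  they are written to JSON with 17 significant digits, which round-trips
  IEEE doubles exactly; a reloaded model reproduces z-scores bit for bit.

## 3. Cognitive status and event times

Global cognition is screened with the MoCA (0–30). The recommended
education correction adds one point for twelve or fewer years of
schooling; the package caps the corrected score at the instrument
ceiling of 30 (the instrument cannot exceed its maximum; the source
analyses are silent on the cap, and it affects only raw scores of 30).
Status cut-offs on the adjusted score are PD-specific: intact ≥ 26,
CI ≤ 25, PDD ≤ 21. A PDD-range score implies CI for event purposes.

Event derivation scans each subject's visit sequence in month order and
applies a **first-crossing rule**: CI onset is the month of the first
visit at or below 25, PDD onset the first at or below 21; a first
crossing directly into the PDD range sets both events at the same month.
Subjects who never cross are right-censored at their last MoCA visit.
Whether a single sub-threshold visit should count as onset, or whether
the decline must be sustained, is not decidable from a single reported
onset month per subject; the package defaults to first crossing (one
visit) and exposes a `sustained = k` argument that requires `k`
consecutive sub-threshold visits and dates onset to the first of the
run. Onset is assigned to the (jittered) visit month itself, measured
from the baseline visit, not to an interval midpoint; events at the
year-1 battery visit are allowed — the earliest observable onset is
therefore about 11 months, matching the shortest retest interval.

Cohort inclusion mirrors the emulated study: an education-adjusted
baseline MoCA in the intact range *and* a one-year follow-up battery;
exclusions are tallied by reason.

## 4. The inferential battery

* **Group comparisons.** Per test and for the composite, OLS of the
  oriented z on a PD indicator (PD = 1), age, sex and education. The PD
  coefficient is the adjusted deficit in residual-SD units.
* **Change-category chi-square.** Pearson goodness-of-fit of the PD
  decline / no-change / improvement counts against expected counts from
  a reference distribution. Two references are implemented because the
  natural choices genuinely differ: the observed HC proportions, and the
  theoretical normal tails (0.05 / 0.90 / 0.05). The HC reference is the
  default; when an HC category is empty while PD observations fall in it
  (which happens in practice — controls may show no declines at all on a
  test) the statistic is undefined and the pipeline falls back to the
  theoretical reference with a logged note. Degrees of freedom are the
  number of non-degenerate categories minus one.
* **Cox proportional hazards.** Within PD only: time to CI, and time to
  PDD, with the oriented z (per test or composite), age and sex as
  covariates. Hazard ratios are per 1-unit z, so HR < 1 means smaller
  practice effects carry higher risk. Ties use the **Efron
  approximation**: onset times concentrate at annual visit months, so
  ties are heavy and the Breslow approximation would be noticeably
  biased. Confidence intervals are Wald-based, matching conventional
  HR (95% CI) reporting. Models with fewer than two events among
  complete cases, or a constant predictor, return a flagged
  not-estimable row rather than failing — with a rare outcome and a
  sparsely administered test, zero events among complete cases is an
  expected configuration, not an error.
* **Diagnostics.** The proportional-hazards assumption is tested
  globally on scaled Schoenfeld residuals; linearity by regressing
  martingale residuals on the predictor and its square. A significant
  quadratic term triggers mean-centering of the predictor, which leaves
  the HR invariant (a location shift of a Cox covariate) — an invariance
  the test suite asserts at `1e-8`.
* **FDR.** Benjamini–Hochberg, applied to flat arrays forming two
  families: one pooling the linear group-comparison p-values with the CI
  Cox p-values, one pooling them with the PDD Cox p-values. The linear
  q-values reported come from the CI family.
* **Median-split curves.** For display only: subjects are split at the
  median oriented z, ties to the low half (deterministic), and
  Kaplan–Meier curves are reported as cumulative incidence $1 - S(t)$.

## 5. The synthetic cohort generator

The generator exists so that every stage above is testable, with known
ground truth, on data with the structure the analysis assumes. Its
defaults emulate a PPMI-like cohort: 214 HC and 547 PD subjects, ages
~N(61.3, 10.5²) truncated to 29–83, ~60% male, education 5–20 years, a
baseline battery with per-test availability matching the emulated
study's participant counts, a one-year battery at a retest interval
drawn uniformly from 11–13 months (the interval is a regression
covariate, so it must vary), and annual MoCA visits to 132 months with
±2 months of jitter and a per-visit retention probability of 0.92 after
year 1. Scores are rounded to integer points (seconds for the timed
tests) and truncated to each test's legal range.

**Latent structure.** One standardized latent practice ability $a_i$ per
subject drives everything: HC ability is N(0, 1), PD ability is
N(−1.5, 1). Follow-up scores are generated as the normative prediction
plus $\sigma_t\,(\lambda_t a_i + e_i)/\sqrt{1+\lambda_t^2}$ with unit
noise $e_i$, so the conditional score SD is $\sigma_t$ for both groups
and the expected PD deficit in residual-SD units is
$\lambda_t/\sqrt{1+\lambda_t^2}$ times the ability shift. The user-facing
calibration is on the z scale: `deficit` is the target mean PD shortfall
in oriented residual-SD units and is converted internally to the loading
$\lambda_t$. This parameterization was chosen over a raw loading because
the largest observed deficits (~1.15 z-units on TMT-B) are not
representable as a loading under a unit ability shift, and because the z
scale is the one group-comparison betas estimate — the recovery tests
close exactly on it. Per-test default deficits are the emulated study's
group betas (0.20 LNST, −0.11 BNT, 0.36 SDMT, 0.13 SFT, 0 JoLO, 0.95
TMT-A, 1.15 TMT-B, 0.25/0.04 HVLT-R); the baseline-score means/SDs per
group and the follow-up targets come from the same study's descriptive
table, with a test–retest correlation of 0.75 fixing the baseline slope
and residual noise.

**Event times.** CI onset follows a Weibull proportional-hazards law
with linear predictor $\beta_{\mathrm{sim}}\,(-a_i)$ — lower ability,
proportionally higher hazard — sampled by inversion; PDD onset adds an
independent positive Weibull gap. The default calibration (shape 0.65,
scale 3000 months, $\beta_{\mathrm{sim}} = 1.0$; gap shape 0.5, scale
700) was chosen, by simulation over the default follow-up schedule, so
that the *observed* outcome mix matches the emulated study: ≈39% of PD
subjects reach CI and ≈10% PDD before censoring, with median observed
onsets near 23 and 50 months. The decreasing-hazard shapes (< 1) are
what produce the front-loaded onset distribution — many conversions at
the first annual visits, a long thin tail thereafter — together with the
strong frailty induced by the ability spread.

**MoCA rendering.** Visits before CI onset draw an integer adjusted
MoCA from 26–30, visits between CI and PDD onset from 22–25, and visits
after PDD onset from ≤ 21. With the default `moca_noise = 0` the first
threshold crossings therefore reproduce the generative onsets *exactly*,
and the test suite asserts this round trip across 20 seeds; positive
noise adds integer Gaussian fluctuation before clipping to 0–30, which
deliberately breaks the exactness in a controlled way. Raw scores are
stored by inverting the education correction, so classification is
consistent for every education level.

**What the generator does not emulate.** Item-level content and
alternate-form difficulty, medication state, informative (outcome-
dependent) dropout, within-state MoCA trends, correlated test-specific
abilities beyond the single factor, and missingness mechanisms other
than independent per-test availability. Passing tests therefore certify
the *pipeline* — its algebra, its event logic, its error control — under
a data-generating process that matches the analysis assumptions; they do
not certify that real PD cohorts satisfy those assumptions.

## 6. Error control and recovery checks

The test suite ties the implementation to independent long-form oracles
(normal-equations OLS, grid-search Cox partial likelihood, brute-force
BH step-up, hand-summed Pearson statistics, long-form product-limit
curves) and runs simulation studies at deliberately chosen problem
sizes: deficit recovery uses 200 replicates at the emulated group sizes
(214/547); calibration checks use 50 replicates of 547 PD subjects;
null-behaviour checks (type-I error of the group comparison and the Cox
test in [0.03, 0.07] at α = 0.05, HR interval coverage near 95%) use 500
replicates of a reduced 60 HC / 90 PD single-test cohort with a denser
baseline hazard — size-free properties, so the reduction changes nothing
but runtime.

## 7. Known limitations

* CI/PDD status is defined by a screening instrument threshold, not a
  clinical diagnosis with functional criteria; the package deliberately
  classifies what the screen supports and exposes the thresholds as
  configuration rather than encoding diagnostic criteria it cannot
  verify.
* The first-crossing rule treats a single sub-threshold visit as onset;
  with noisy MoCA measurements this overstates incidence relative to a
  sustained-decline definition (the `sustained` argument quantifies the
  sensitivity).
* Whether subjects whose CI and PDD onsets coincide should contribute to
  PDD models is not specified by the emulated analysis; they are
  retained.
* The SRB model is linear with homoscedastic residuals; ceiling-heavy
  tests (e.g., JoLO) mildly violate this, which is visible in the
  simulator's truncation but not corrected in the scoring model.
* No competing-risk treatment of death or dropout, no time-varying
  covariates, no imputation of missing tests.
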