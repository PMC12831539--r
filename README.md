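# practicefx

Practice effects — the score gains people show simply from having taken a
cognitive test before — are usually treated as nuisance variance in
longitudinal neuropsychology. In Parkinson's disease (PD) they carry
signal: patients whose one-year retest gains are *smaller than expected*
are at elevated risk of progressing to cognitive impairment (CI) and
dementia (PDD). `practicefx` packages that analysis for biostatisticians
and neuropsychology researchers working with longitudinal cohorts of the
PPMI type (a baseline + one-year nine-test battery, annual MoCA visits
over five or more years), together with a fully synthetic cohort
generator so every stage can be exercised and validated without access to
restricted patient data.

## The method

**SRB change scores.** For each test, a normative standardized
regression-based (SRB) equation is fitted on healthy controls by ordinary
least squares:

    y₁ = β₀ + β₁·y₀ + β₂·age + β₃·sex + β₄·education + β₅·interval + ε

where `y₀`, `y₁` are baseline and one-year scores. A subject's practice
effect is the standardized residual

    z = (y₁ observed − y₁ predicted) / σ̂ε ,   σ̂ε² = RSS / (n − 6)

so `z` measures how much more (or less) a subject improved than a
demographically matched control. Scores on the timed Trail Making tests
are sign-reversed so positive always means better than expected. Each `z`
is trichotomized at the 5% normal tails (decline ≤ −1.645, improvement
≥ 1.645), and a composite averages six designated tests (LNST, SDMT, SFT,
JoLO, HVLT-R immediate/delayed).

**Cognitive status.** Education-corrected MoCA (+1 point for ≤ 12 years
of schooling, capped at 30) classifies each visit as intact (≥ 26), CI
(≤ 25) or PDD (≤ 21); first threshold crossings give per-subject event
indicators and onset months, with right censoring at the last visit.

**Inference.** Group differences in `z` (PD vs HC) by linear regression
adjusting for age, sex and education; change-category distributions by
Pearson chi-square against the HC (or theoretical 5/90/5) reference; risk
by Cox proportional hazards (`HR` per 1-unit `z`; HR < 1 means smaller
practice effects carry higher risk), with Schoenfeld-residual and
martingale-linearity diagnostics; Benjamini–Hochberg FDR per outcome
family; and median-split cumulative-incidence curves for display.

**Synthetic cohorts.** A single latent practice ability per subject
drives both the per-test gain deficits in PD and a Weibull proportional
hazard of progression, so the practice-effect → outcome association
exists with known ground truth; with zero MoCA noise the generative onset
times are recovered *exactly* by the classification stage.

## Worked example

```r
library(practicefx)
res <- run_pipeline(sim_config(seed = 3))

gc <- res$analysis$group_comparisons
gc[gc$test %in% c("SDMT", "TMT_B", "composite"), ]
#>       test beta_group     se        p   n        q
#>       SDMT     -0.382 0.0798 2.07e-06 761 1.38e-05
#>      TMT_B     -0.994 0.2473 9.82e-05 135 3.93e-04
#>  composite     -0.133 0.0331 6.29e-05 761 3.15e-04
```

PD subjects gain ~0.38 residual-SD less than controls on the SDMT and
~1 SD less on TMT-B (`beta_group` is the adjusted PD − HC difference in
SRB z-units; `q` is the FDR-adjusted p).

```r
cox <- res$analysis$cox
cox[cox$outcome == "CI" & cox$predictor %in% c("composite", "SDMT"),
    c("predictor", "hr", "ci_low", "ci_high", "p", "q", "n_events")]
#>  predictor    hr ci_low ci_high       p        q n_events
#>  composite 0.592  0.430   0.814 0.00127 0.003167      225
#>       SDMT 0.773  0.675   0.884 0.00018 0.000599      225
```

Each 1-unit increase in the composite practice-effect z lowers the CI
hazard by ~41% (HR 0.59): smaller practice effects, higher risk.

```r
out <- res$outcomes
sprintf("CI: %d/%d (%.0f%%), median onset %.0f months",
        sum(out$ci_event), nrow(out), 100 * mean(out$ci_event),
        median(out$ci_time[out$ci_event]))
#> "CI: 225/547 (41%), median onset 26 months"
#> "PDD: 50/547 (9%), median onset 60 months"
```

A command-line wrapper with `simulate`, `fit-norms`, `score`,
`classify`, `analyze` and `run-all` verbs is installed at
`inst/cli/practicefx.R`.

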