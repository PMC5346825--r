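# crweibull

Parametric competing-risks survival analysis with cause-specific Weibull
hazards, for right-censored cohort studies in which patients can die of
the disease under study or of other causes. The package is aimed at
biostatisticians analysing prognostic-factor cohorts (the shipped
defaults emulate a colorectal-cancer registry with two competing causes
of death), and at methodologists who need a fully specified, testable
data-generating process for competing-risks simulations.

## The model

Each cause of failure j = 1, ..., K gets its own Weibull survival
function

    S_j(t; x) = exp(−λ_j(x) · t^{p_j}),      λ_j(x) = exp(x·β_j),

so the cause-specific hazard h_j(t; x) = λ_j(x) p_j t^{p_j−1} is
proportional in the covariates and every coefficient exponentiates to a
time-constant cause-specific hazard ratio. The design row is
(1, bmi, age, woman, stage II, stage III, stage IV), with man and
stage I as reference levels. Estimation is maximum likelihood on the
cause-specific likelihood, which separates across causes (failures from
other causes enter as censored); inference is Wald:
HR = exp(β̂), 95% CI = exp(β̂ ± 1.959964·SE), observed-information
standard errors.

On top of the fit the package provides:

* `fit_naive()` — the single-event Weibull comparator that ignores
  competing risks (cause-1-only or any-death event definitions);
* `kaplan_meier()`, `cloglog_points()`, `weibull_linearity()` — the
  log(−log S) vs log t adequacy diagnostic (linear with slope p under a
  Weibull law);
* `cumulative_incidence()`, `curve_grid()`, `survival_at_horizon()` —
  model-based cumulative incidence F_j(t) = ∫₀ᵗ h_j(u)S(u)du and
  five-year stage-specific summaries, with S + ΣF_j = 1 enforced to
  quadrature tolerance;
* `generate_cohort()` — a synthetic cohort generator with latent
  per-cause Weibull times, covariate margins matching the emulated
  registry (n = 372, 56.7% men, stage mix 31.5/29.6/31.2/7.8%), and
  ~66% right-censoring.

## Worked example

```r
library(crweibull)

d <- generate_cohort(generator_config(n = 372, seed = 7))
summarize_cohort(d)
#> Cohort of 372 subjects, 2 competing cause(s)
#>   censored    249 (66.9%)
#>   cause1      108 (29.0%)
#>   cause2       15 (4.0%)
#>   age  mean 51.91 sd 14.63
#>   bmi  mean 24.47 sd 3.84
#>   time mean 50.98 sd 35.01 median 44.8 (P25 21.8, P75 77.9)

fit <- fit_competing(d)
hazard_ratio(fit$fits[[1]], "stage_IV")
#>   covariate coef    se   hr ci_low ci_high  p_value
#> 1  stage_IV 1.81 0.287 6.09   3.48    10.7 2.83e-10

lin <- weibull_linearity(cloglog_points(kaplan_meier(d)))
#> cloglog slope 0.963, R^2 0.989

survival_at_horizon(fit, horizon = 60)   # cause-1 rows:
#>     profile surv_cause   cif
#>     stage_I      0.754 0.245
#>    stage_II      0.855 0.141
#>   stage_III      0.613 0.380
#>    stage_IV      0.179 0.778
```

Reading the output: the simulated cohort reproduces the registry event
mix (29% colorectal-cancer deaths, 4% other-cause deaths, 67%
censored). Stage IV carries a cause-specific hazard ratio of 6.1
(95% CI 3.5–10.7) for colorectal-cancer death relative to stage I in
this realization. The cloglog diagnostic is near-linear (R² = 0.989)
with slope ≈ 1, consistent with the generating shape of 1.1. At 60
months, `surv_cause` is the cause-1 Weibull survival
exp(−λ₁·60^{p₁}) and `cif` the probability of having died of cause 1
with the competing cause operating; the two columns answer different
questions and are both reported.

A cause whose likelihood degenerates (for example no events in a stage
category, which sends that coefficient to −∞) is flagged
`divergent`/non-converged rather than silently returned —
`survival_at_horizon()` refuses such fits.

## Analysis pipeline

The `analysis/` directory is a numbered, self-contained walk through
the whole study on a simulated cohort, writing its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R   # cohort + truth table + baseline summary
Rscript analysis/02_fit.R        # competing + naive fits, HR tables
Rscript analysis/03_diagnose.R   # cloglog diagnostic + plot
Rscript analysis/04_curves.R     # stage-specific curves, 5-year summaries
```

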