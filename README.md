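# growthspurt

Tools for studying the adolescent growth spurt in longitudinal cohorts —
built for epidemiologists analysing height trajectories of children on
long-term treatment (the motivating setting is paediatric HIV cohorts
starting antiretroviral therapy at ages 1–10), but applicable to any
longitudinal anthropometry with per-subject covariates.

## What it does

The core is a shape-invariant (SITAR) nonlinear mixed model. One natural
cubic spline *h(t)* carries the common shape of height growth over age, and
each subject deforms it with three parameters:

    y_it = a_i + h((t − b_i) · exp(c_i)) + ε_it,   ε_it ~ N(0, σ²)

* **a** — size (cm): vertical shift, average height through adolescence;
* **b** — timing (years): horizontal shift, positive = later growth spurt;
* **c** — intensity (log-rate): age-axis compression, positive = steeper,
  shorter spurt.

Each parameter has covariate fixed effects on its mean plus a subject-level
random effect (unstructured 3×3 covariance). Estimation alternates
first-order linearization with a penalized mode refinement
(Lindstrom–Bates style); velocity curves are analytic derivatives, and the
age at peak height velocity obeys `APHV = b + u0·exp(−c)`.

Around the model the package provides:

* an LMS z-score engine (`lms_zscore`, `lms_inverse`,
  `reference_mean_sd`) with WHO stunting / BMI categories and the
  standard-below-5 / reference-from-5 switch;
* cohort-construction rules with an attrition ledger
  (`apply_inclusion`, `censor_visits`, `baseline_anthropometry`,
  `flag_implausible`, `build_cohort`);
* Wald contrasts between covariate profiles (`sitar_contrast`), BIC model
  comparison, plain-text fit serialization;
* a second-stage OLS of the subject-level effects on clinical covariates
  with interaction screening (`second_stage_regression`);
* a synthetic-cohort generator with exported ground truth
  (`simulate_cohort`), used throughout the tests;
* an end-to-end driver (`run_study`) and a small CLI
  (`inst/exec/growthspurt`).

The LMS tables shipped under `inst/extdata` are **synthetic** stand-ins
(Preece–Baines medians calibrated to published WHO 2007 summary values at
age 16: boys 173 cm / SD 7.8, girls 163 cm / SD 6.8); real analyses supply
their own tables as `age_months,L,M,S` CSVs.

## Worked example

Simulate a cohort of 200 girls whose most stunted group has a true
1.5-year timing delay, build the analysis cohort, fit the model and read
off the delay:

```r
library(growthspurt)

cfg  <- synthetic_config(n_subjects = 200, sex_ratio_male = 0)
coh  <- simulate_cohort(cfg, seed = 42)
refs <- default_reference_set()

bundle <- build_cohort(coh$subjects, coh$visits, refs)
fit <- sitar(height_cm ~ age_years | subject_id, bundle$visits,
             covariates = coh$subjects,
             a_formula = ~ haz_group, b_formula = ~ haz_group)
fit
#> SITAR growth model (natural spline, df = 6 )
#>   7705 observations, 200 subjects; logLik -9801.22; sigma 0.700 cm
#>   converged: TRUE after 34 iterations

lv  <- levels(coh$subjects$haz_group)
ref <- data.frame(haz_group = factor("normal", lv))
sev <- transform(ref, haz_group = factor("severe_stunting", lv))
sitar_contrast(fit, "b", sev, ref)
#> Contrast on b: 1.385 years (95% CI 1.023 to 1.746), p = 6.018e-14

height_at_16(bundle, refs)
#>      sex   n     mean      sd ref_mean ref_sd         t            p
#> 1 female 189 155.9072 8.54808      163    6.8 -11.40728 3.031655e-23
```

The contrast recovers the generating 1.5-year delay within its confidence
interval (the measurement noise σ = 0.7 cm is recovered exactly here), and
the cohort is about 7 cm shorter at 16 than the reference — by
construction, since the generator gives stunted groups negative size
effects.

`run_study(study_config(), out_dir)` runs the whole pipeline (eligibility
ledger, baseline table, sex-stratified fits, contrasts, curve grids,
height-at-16 comparison, second-stage regression) and writes CSV outputs
that are byte-identical under a fixed seed.

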