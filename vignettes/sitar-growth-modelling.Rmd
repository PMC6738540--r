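---
title: "Shape-invariant modelling of the adolescent growth spurt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-invariant modelling of the adolescent growth spurt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`growthspurt` models longitudinal height during adolescence with a
shape-invariant (SITAR) mixed model. One natural cubic spline `h(t)`
describes the common shape of growth in height over age, and each subject
deforms it with three parameters:

$$y_{it} = a_i + h\big((t - b_i)\,e^{c_i}\big) + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \sigma^2).$$

* `a` (**size**, cm) shifts the whole curve up or down; negative values mean
  a shorter child throughout adolescence.
* `b` (**timing**, years) shifts the curve along the age axis; positive
  values mean a *later* growth spurt.
* `c` (**intensity**, log-rate) stretches or compresses the age axis;
  positive values mean a steeper, shorter spurt with a higher peak
  velocity.

Each subject parameter is the sum of covariate fixed effects on its mean
(for example baseline height-for-age group and age band at ART initiation)
and a subject-level random effect; the three random effects share an
unstructured $3\times 3$ covariance $\Omega$. The growth-velocity curve is
the analytic first derivative of the fitted distance curve,
$v(t) = e^{c}\,h'((t-b)e^{c})$, and the age at peak height velocity (APHV)
is its maximiser, which obeys the closed form
$\mathrm{APHV} = b + u_0 e^{-c}$ with $u_0$ the peak of the population
curve. Because velocity curves need not be unimodal over wide ranges (a flat
pre-pubertal plateau precedes the spurt), `aphv()` scans a coarse grid
before golden-section refinement.

### Assumptions

* A single common curve shape per stratum: models are fitted separately by
  sex, since boys and girls differ in curve shape, not just in the three
  deformation parameters.
* Gaussian, homoscedastic measurement error in cm, independent across
  visits.
* Random effects are jointly Gaussian with mean zero given the covariate
  fixed effects; censoring (transfer, loss to follow-up) is noninformative
  for the growth process.

## Estimation

The marginal likelihood has no closed form, so fitting alternates the two
halves of the classic first-order linearization scheme for nonlinear mixed
models:

1. **Linearize** the model in all three subject parameters around the
   current fixed-effect estimates and empirical-Bayes modes, producing a
   working response and derivative design columns
   ($\partial y/\partial b = -e^{c} h'(u)$,
   $\partial y/\partial c = u\,h'(u)$).
2. **Solve** the resulting linear mixed model by maximum likelihood
   (`lme4::lmer`), updating the spline coefficients, all fixed effects,
   $\Omega$ and $\sigma$ in one pass.
3. **Refine the modes** by penalized Gauss-Newton per subject (the
   penalized nonlinear least-squares half of the alternation). A single
   linear-solve update of the modes lags the posterior optimum and
   measurably attenuates covariate contrasts; the refinement removes that.
4. **Recenter**: the covariate-explained projection of the modes is moved
   into the fixed effects. Subject-level totals, and hence the likelihood,
   are unchanged, but without this step the fixed/random split can drift
   along a likelihood-flat ridge and group contrasts read from the
   coefficients are attenuated.

The proposal from each pass is accepted with step-halving damping: if the
working objective decreases, the step toward the proposed update is halved,
so the accepted objective trace is non-decreasing by construction. When
continuous updates stall, one discrete escape move re-aligns each subject's
timing mode by grid search against the current curve (penalized by the
current prior) and is accepted only if the objective improves. Iteration
stops when the relative change in the working log-likelihood falls below
`1e-6` (`sitar_control(tol=)`), with a cap of 200 passes.

Two further choices matter in practice:

* **Warm start.** The pooled spline blurs the spurt, and starting every
  subject at `b = 0` can strand the alternation in a local optimum in which
  timing effects are shrunk toward zero. Before iterating, each subject is
  grid-aligned to the pooled curve (best time shift after refitting the
  subject intercept, grid ±2.5 y by 0.25), the spline is refit at those
  shifts, and the alignment is repeated once.
* **Boundary knots.** Interior knots sit at equally spaced quantiles of the
  observed ages, but the boundary knots are placed 10% *beyond* the
  observed age range. With boundary knots at the data range, subjects with
  nonzero timing shifts are evaluated on the spline's linear tails, which
  systematically attenuates timing contrasts; the extension keeps
  transformed ages in the cubic interior. (Reference implementations of
  this model family likewise extend their bounds beyond the data range.)

Identifiability: all three parameters estimate fixed intercepts. The
timing and intensity intercepts are weakly identified against the freely
estimated spline — a flat ridge — but they give the global mode means a
home, so the empirical-Bayes effects stay centred; contrasts between
covariate profiles never involve the intercepts.

The fixed-effect covariance is taken from the final linearized step and
contrasts use normal-quantile (Wald) 95% intervals. `BIC` is
$-2\ell + k\log n_{\text{obs}}$ with `k` counting spline coefficients,
fixed effects, covariance terms and $\sigma$; `compare_models()` breaks
ties toward fewer parameters. Near-singular $\Omega$ (condition number
above `1e8`) triggers a diagonal-covariance refit with a warning.
Degenerate inputs fail fast: fewer than two subjects, or fewer distinct
ages than spline degrees of freedom, are rank errors, as are aliased or
empty-level covariate designs. Internally observations are sorted by
(subject, age, value), so the fit is exactly invariant to input row order.

Log transformations of age and height are available
(`log_age`, `log_height`) but off by default; untransformed height over age
is the default analysis scale.

## The z-score engine

Reference distributions are age-indexed LMS tables (skewness power L,
median M, coefficient of variation S), linearly interpolated in age (in
months), with no extrapolation beyond the table ends. Scoring uses the
growth *standard* below exactly age 5 and the *reference* from age 5
upward, matching the "under 5 years" convention. The reference SD at an
age is defined as half the distance between the measurements at $z = \pm1$,
which equals $M\cdot S$ when $L = 1$ and stays correct for skewed
references. Category boundaries are half-open exactly as defined by WHO:
height-for-age at $-3, -2, -1$ with lower bounds inclusive; BMI-for-age
with the normal band closed at $+1$ and open above. Scores beyond typical
validity flags (|z| > 5) are neither truncated nor dropped; downstream
implausibility checks handle genuinely impossible *changes*.

The packaged LMS tables under `inst/extdata` are **synthetic**: medians are
monotone Preece-Baines curves rescaled so that the mean and SD at age 16.0
equal published WHO 2007 summary values (boys 173 cm / 7.8; girls 163 cm /
6.8), with constant S for height and a mildly skewed (L = -1.5) profile for
BMI. They give every example and test a realistic, fully reproducible
substrate without bundling third-party tables; production analyses pass
their own `lms_reference_set()` (e.g. real WHO or national tables) in the
same CSV format.

## Cohort construction

Eligibility is applied in a fixed order with an attrition ledger:
eligible regimen (NNRTI- or boosted-PI-based), age 1 to <11 years at ART
initiation, no known horizontal acquisition, at least 8 years old at the
end of follow-up, a height within the baseline window, and a height after
age 8. The baseline window runs from 6 months before to 1 month after ART
initiation; the visit nearest in absolute offset wins and exact ties go to
the pre-ART visit, on the grounds that a pre-treatment measurement is
uncontaminated by early treatment effects (configurable). The modelling
window keeps measurements between `max(8, ART-initiation age)` and 18
years, truncated at the end of follow-up (earliest of 19th birthday,
transfer, death, loss to follow-up); censoring is idempotent.

Implausible-change checks are configurable defaults, not published rules: a
height decrease of more than 2 cm between consecutive visits, or an
absolute height-for-age z-score change above 2 between visits less than a
year apart, flags the later visit; flagged visits are dropped by default
but can be kept. Baseline tables report counts (%) for categorical and
median (IQR) for continuous covariates by height-for-age category, with
global heterogeneity tests (chi-square / Kruskal-Wallis); trend tests are
not implemented. The height-at-16 comparison takes each subject's
measurement nearest the 16th birthday within half a year and runs a
one-sample t-test against the reference mean at 16 (for a degenerate
constant sample the statistic is defined by its limit).

The second stage regresses each subject's empirical-Bayes `a_i`, `b_i`,
`c_i` on clinical covariates by OLS on complete cases only (no imputation),
with Wald 95% intervals. Candidate interactions are screened by F-test and
reported as retained when p < 0.05. When a run analyses a single sex or
stratum, covariates that no longer vary are dropped from the default
design automatically.

## The synthetic-data generator

`simulate_cohort()` is first-class, tested code: it generates cohorts with
the statistical structure the analysis assumes, plus exported ground truth
for recovery tests. The generating mean curve is Preece-Baines model 1 —
smooth, monotone, with a single analytic velocity peak — deliberately *not*
a spline, so the estimator is never tested against its own basis. Defaults
emulate a pooled paediatric HIV cohort initiating ART at ages 1-10:
covariate marginals near the published mix (48% male; height-for-age groups
14/17/25/44%; Thailand/UK-Ireland/other 32/47/21%; 80% NNRTI; ART-year
periods 40/40/20%), visit spacing averaging 2.8 months with jitter,
follow-up censored at the earliest of the 19th birthday, transfer (35%
risk, uniform 16-19 y), loss to follow-up (8%) or death (1%), and additive
true effects on the three parameters, including a 1.5-year timing delay for
the most stunted group and a 0.41-year delay for the oldest ART-initiation
band. Random effects default to SDs of 5 cm (size), 0.8 y (timing) and 0.1
(intensity) with a mild 0.2 size-timing correlation, and measurement noise
to 0.7 cm — plausibility-based values, since no published variance
components were available to calibrate against. All randomness flows from
one seeded stream, so outputs are byte-identical given `(config, seed)`.

What the generator does *not* emulate: the joint covariate distribution
beyond configurable marginals, outcome-dependent (informative) censoring,
cohort-level measurement heterogeneity, secular trends, or missing-data
mechanisms beyond baseline-window misses and censoring. Passing recovery
tests therefore demonstrates that the estimation machinery is correct and
calibrated under the stated assumptions — not that those assumptions hold
in any particular real cohort.

## Problem sizes in the test-suite

The package's own validation uses synthetic cohorts of 500 subjects (about
20,000 measurements) for parameter-recovery checks, with 10 replicate fits
for the headline timing-delay recovery, 50 replicates for the second-stage
interaction power check (chosen a priori: a 0.5-year interaction effect
against a 0.8-year subject SD at n = 500 gives a Wald SE near 0.14 and
about 94% power), and smaller cohorts (40-150 subjects) for pipeline,
serialization and determinism checks. These sizes were chosen so the whole
suite exercises the full pipeline at realistic scale while remaining quick
to run on a single CPU.

## Known limitations

* The likelihood is the first-order linearized approximation, not an exact
  (quadrature) marginal likelihood; no Bayesian posterior is available.
* A single outcome (height) is modelled; BMI enters only through z-scores
  as a covariate.
* The timing/intensity fixed intercepts ride a flat likelihood ridge
  against the spline; their own standard errors are not interpretable
  (contrasts are unaffected).
* Reference tables are linearly interpolated between rows; supply
  fine-grained (monthly) tables for maximal accuracy.
* The synthetic cohort is a stylised emulation; see the generator section
  for what it deliberately leaves out.
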