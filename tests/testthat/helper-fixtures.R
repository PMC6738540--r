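# shared fixtures, built in code; heavyweight fits are cached per session

# independent oracle: natural cubic spline via the truncated-power
# construction.  d_k(x) = ((x - k)_+^3 - (x - K)_+^3) / (K - k) with K the
# last knot; the natural basis is {1, x, d_k - d_{K-1}} over all knots.
tp_natural_basis <- function(x, knots) {
  K <- sort(knots)
  m <- length(K)
  dk <- function(k) (pmax(x - k, 0)^3 - pmax(x - K[m], 0)^3) / (K[m] - k)
  base <- vapply(K[seq_len(m - 2L)],
                 function(k) dk(k) - dk(K[m - 1L]), numeric(length(x)))
  cbind(1, x, base)
}

# flat LMS tables (L = 1, M = 100, S = 0.05 unless overridden) covering both
# the standard (<5 y) and reference (>= 5 y) segments
flat_refs <- function(L = 1, M = 100, S = 0.05) {
  tab <- function(ages, sex) load_lms_table(
    data.frame(age_months = ages, L = L, M = M, S = S), "height", sex)
  lms_reference_set(
    standard = list(tab(c(0, 60), "male"), tab(c(0, 60), "female")),
    reference = list(tab(c(60, 228), "male"), tab(c(60, 228), "female")))
}

# small all-female cohort with the default generating conditions plus its fit;
# cached because several test files interrogate the same model
.fixture_cache <- new.env(parent = emptyenv())

cached_girls_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    cfg <- synthetic_config(n_subjects = 120, sex_ratio_male = 0)
    coh <- simulate_cohort(cfg, seed = 7)
    vis <- censor_visits(coh$visits, coh$subjects)
    fit <- sitar(height_cm ~ age_years | subject_id, vis,
                 covariates = coh$subjects,
                 a_formula = ~ haz_group + age_group,
                 b_formula = ~ haz_group + age_group)
    .fixture_cache$cohort <- coh
    .fixture_cache$visits <- vis
    .fixture_cache$fit <- fit
  }
  list(fit = .fixture_cache$fit, cohort = .fixture_cache$cohort,
       visits = .fixture_cache$visits)
}

# a smooth sitar_curve fitted to the female generating curve, for the
# curve-algebra tests (known, closed-form oracle alongside)
pb_sitar_curve <- function() {
  if (is.null(.fixture_cache$curve)) {
    crv <- pb1_curve(163.3, 152.5, 0.10, 1.00, 12.3)
    tg <- seq(6, 20, by = 0.05)
    gen <- ncs_basis(tg, df = 8)
    co <- stats::lm.fit(cbind(1, gen$basis), crv$height(tg))$coefficients
    .fixture_cache$curve <- sitar_curve(gen, co[-1], intercept = co[1])
    .fixture_cache$pb <- crv
  }
  list(curve = .fixture_cache$curve, pb = .fixture_cache$pb)
}
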