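test_that("noise-free data from a known curve are recovered exactly", {
  # truth generated on the same basis the fit will build (quantile knots of
  # the same pooled ages), with all subject effects zero
  set.seed(5)
  n_sub <- 25
  ages <- lapply(seq_len(n_sub), function(i) seq(8, 18, by = 0.5))
  tt <- unlist(ages)
  rng <- range(tt)
  gen <- ncs_basis(tt, df = 6, boundary = rng + c(-0.1, 0.1) * diff(rng))
  co <- stats::lm.fit(cbind(1, gen$basis),
                      pb_sitar_curve()$pb$height(tt))$coefficients
  truth <- drop(cbind(1, gen$basis) %*% co)
  d <- data.frame(subject_id = rep(sprintf("S%02d", seq_len(n_sub)),
                                   lengths(ages)),
                  age_years = tt, height_cm = truth)
  fit <- sitar(height_cm ~ age_years | subject_id, d)
  expect_true(fit$converged)
  expect_lt(fit$sigma, 0.05)
  eff <- subject_effects(fit)
  expect_lt(max(abs(unlist(eff[, c("a_i", "b_i", "c_i")]))), 1e-3)
  expect_lt(max(abs(fitted(fit) - truth)), 1e-2)
})

test_that("refitting with permuted subject order is invariant", {
  cfg <- synthetic_config(n_subjects = 40, sex_ratio_male = 0)
  coh <- simulate_cohort(cfg, seed = 13)
  vis <- censor_visits(coh$visits, coh$subjects)
  ctrl <- sitar_control(tol = 1e-10, max_iter = 300)
  fit1 <- sitar(height_cm ~ age_years | subject_id, vis,
                covariates = coh$subjects, b_formula = ~ haz_group,
                control = ctrl)
  ord <- order(factor(vis$subject_id, levels = rev(unique(vis$subject_id))))
  fit2 <- sitar(height_cm ~ age_years | subject_id, vis[ord, ],
                covariates = coh$subjects, b_formula = ~ haz_group,
                control = ctrl)
  expect_lt(max(abs(fit2$beta[fit2$index$b] - fit1$beta[fit1$index$b])),
            1e-6)
  expect_lt(abs(fit2$loglik - fit1$loglik), 1e-5)
  e1 <- subject_effects(fit1)
  e2 <- subject_effects(fit2, subject_ids = e1$subject_id)
  expect_lt(max(abs(e2$b_i - e1$b_i)), 1e-6)
})

test_that("a single subject cannot identify the model", {
  d <- data.frame(subject_id = "S1", age_years = seq(8, 18, 0.25))
  d$height_cm <- 120 + 4 * (d$age_years - 8)
  expect_error(sitar(height_cm ~ age_years | subject_id, d), "rank error")
})

test_that("empirical-Bayes effects are centred and track the truth", {
  fx <- cached_girls_fit()
  eff <- subject_effects(fx$fit)
  expect_identical(nrow(eff), fx$fit$n_subjects)
  # centering: sample mean of each effect within 3 SE of zero
  for (v in c("a_i", "b_i", "c_i")) {
    se <- stats::sd(eff[[v]]) / sqrt(nrow(eff))
    expect_lt(abs(mean(eff[[v]])), 3 * se)
  }
  # subject-level deviations correlate strongly with the generating ones
  tr <- fx$cohort$truth$effects
  m <- match(eff$subject_id, tr$subject_id)
  expect_gt(stats::cor(eff$b_i, tr$b_true[m] - tr$b_mean[m]), 0.8)
  expect_gt(stats::cor(eff$a_i, tr$a_true[m] - tr$a_mean[m]), 0.9)
  expect_error(subject_effects(fx$fit, "NOPE"), "key error")
})

test_that("translation identity: moving size into the intercept is a no-op", {
  cv <- pb_sitar_curve()$curve
  t <- seq(8, 18, by = 0.1)
  cv2 <- cv
  cv2$intercept <- cv$intercept - 4.2
  expect_equal(sitar_mean(cv2, 4.2, 0.3, 0.1, t),
               sitar_mean(cv, 0, 0.3, 0.1, t))
})

test_that("the accepted objective trace never decreases", {
  fx <- cached_girls_fit()
  expect_true(all(diff(fx$fit$trace) >= -1e-8))
})

test_that("contrasts reproduce direct computation from beta and vcov", {
  fx <- cached_girls_fit()
  fit <- fx$fit
  lv <- levels(fx$cohort$subjects$haz_group)
  la <- levels(fx$cohort$subjects$age_group)
  ref <- data.frame(haz_group = factor("normal", lv),
                    age_group = factor("1-2", la))
  sev <- transform(ref, haz_group = factor("severe_stunting", lv))
  cs <- sitar_contrast(fit, "b", sev, ref)
  # by-hand Wald computation: severe_stunting is the design's reference
  # level, so the contrast is minus the "normal" coefficient of the timing
  # block
  j <- fit$index$b[match("haz_groupnormal", names(fit$beta)[fit$index$b])]
  est <- -fit$beta[[j]]
  se <- sqrt(fit$vcov[j, j])
  expect_lt(abs(cs$estimate - est), 1e-12)
  expect_lt(abs(cs$se - se), 1e-12)
  expect_true(cs$ci_low <= cs$estimate && cs$estimate <= cs$ci_high)
  # identical profiles: zero difference, p = 1
  c0 <- sitar_contrast(fit, "b", ref, ref)
  expect_identical(c0$estimate, 0)
  expect_identical(c0$p_value, 1)
  # unknown factor level cannot be scored
  bad <- transform(ref, haz_group = "giant")
  expect_error(sitar_contrast(fit, "b", bad, ref), "design error")
})

test_that("BIC follows -2 logLik + k log(n) and ties go to fewer params", {
  fake <- function(ll, k, n) structure(
    list(loglik = ll, k_params = k, n_obs = n), class = "sitar")
  expect_equal(stats::BIC(logLik(fake(-100, 10, 1000))),
               200 + 10 * log(1000))
  f1 <- fake(-100, 10, 1000)
  f2 <- fake(-100 - 5 * log(1000) / 2, 5, 1000)  # identical BIC, fewer k
  expect_identical(as.integer(compare_models(f1, f2)), 2L)
  expect_identical(as.integer(compare_models(f2, f1)), 1L)
  expect_error(compare_models(f1, fake(-90, 10, 999)), "comparison error")
})

test_that("model comparison prefers the generating design", {
  fx <- cached_girls_fit()
  # drop the timing covariates: the generating model has real timing
  # effects, so the richer model should win on BIC
  fit0 <- sitar(height_cm ~ age_years | subject_id, fx$visits,
                covariates = fx$cohort$subjects,
                a_formula = ~ haz_group + age_group)
  expect_identical(as.integer(compare_models(fit0, fx$fit)), 2L)
})

test_that("predict supports profiles, velocities and subject offsets", {
  fx <- cached_girls_fit()
  fit <- fx$fit
  t <- seq(9, 17, by = 0.5)
  lv <- levels(fx$cohort$subjects$haz_group)
  la <- levels(fx$cohort$subjects$age_group)
  ref <- data.frame(haz_group = factor("normal", lv),
                    age_group = factor("1-2", la))
  base <- predict(fit, t, profile = ref)
  sev <- transform(ref, haz_group = factor("severe_stunting", lv))
  shifted <- predict(fit, t, profile = sev)
  # a later, lower curve for the severely stunted profile around the spurt
  expect_true(mean(shifted - base) < 0)
  # velocity integrates to height gain for the profile
  gain <- stats::integrate(function(x)
    predict(fit, x, profile = sev, what = "velocity"), 9, 17,
    rel.tol = 1e-9)$value
  expect_equal(gain, predict(fit, 17, profile = sev) -
                 predict(fit, 9, profile = sev), tolerance = 1e-5)
})
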