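test_that("the generating curve honours its closed form", {
  crv <- pb1_curve(176.8, 163.0, 0.11, 1.2, 13.9)
  # asymptote and anchor
  expect_equal(crv$height(1e4), 176.8, tolerance = 1e-10)
  expect_equal(crv$height(13.9), 163.0)
  # analytic velocity vs central differences on 50 points
  t <- seq(3, 19, length.out = 50)
  h <- 1e-5
  num <- (crv$height(t + h) - crv$height(t - h)) / (2 * h)
  expect_lt(max(abs(crv$velocity(t) - num)), 1e-6)
  # invariant violations are parameter errors
  expect_error(pb1_curve(160, 163, 0.11, 1.2, 13.9), "parameter error")
  expect_error(pb1_curve(176, 163, 1.2, 0.11, 13.9), "parameter error")
  expect_error(pb1_curve(176, 163, 0.11, 1.2, 20), "parameter error")
})

test_that("simulation is byte-identical per (config, seed)", {
  cfg <- synthetic_config(n_subjects = 40)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$visits, b$visits)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth$effects, b$truth$effects)
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$visits, c$visits))
})

test_that("zero variances and zero effects land every height on the curve", {
  cfg <- synthetic_config(n_subjects = 15, omega = diag(c(0, 0, 0)),
                          sigma = 0, effect_map = NULL)
  coh <- simulate_cohort(cfg, seed = 1)
  crv <- lapply(default_curve_params(), .pb1_from_params)
  sex <- coh$subjects$sex[match(coh$visits$subject_id,
                                coh$subjects$subject_id)]
  expected <- vapply(seq_len(nrow(coh$visits)), function(i)
    crv[[sex[i]]]$height(coh$visits$age_years[i]), numeric(1))
  expect_equal(coh$visits$height_cm, expected, tolerance = 1e-12)
})

test_that("covariate marginals match the configuration at n = 2000", {
  cfg <- synthetic_config(n_subjects = 2000)
  coh <- simulate_cohort(cfg, seed = 5)
  s <- coh$subjects
  checks <- list(
    c(mean(s$sex == "male"), cfg$sex_ratio_male),
    c(mean(s$haz_group == "severe_stunting"),
      cfg$haz_group_probs[["severe_stunting"]]),
    c(mean(s$country_group == "thailand"), cfg$country_probs[["thailand"]]),
    c(mean(s$born_abroad), cfg$born_abroad_rate),
    c(mean(s$regimen == "nnrti"), cfg$nnrti_rate),
    c(mean(s$age_group == "6-10"), cfg$age_band_probs[["6-10"]]))
  for (ck in checks) {
    p <- ck[2]
    expect_lt(abs(ck[1] - p), 3 * sqrt(p * (1 - p) / 2000))
  }
})

test_that("visit schedule and censoring behave as configured", {
  cfg <- synthetic_config(n_subjects = 300)
  coh <- simulate_cohort(cfg, seed = 8)
  m <- match(coh$visits$subject_id, coh$subjects$subject_id)
  # no visit beyond the censoring age, none before ART initiation
  expect_true(all(coh$visits$age_years <= coh$subjects$end_age[m] + 1e-9))
  expect_true(all(coh$visits$age_years >=
                    coh$subjects$art_init_age[m] - 1e-9))
  # median spacing close to the configured 2.8 months
  gaps <- unlist(tapply(coh$visits$age_years, coh$visits$subject_id, diff))
  expect_lt(abs(stats::median(gaps) - cfg$visit_interval_mean), 0.05)
  # subjects followed beyond 16 do have measurements past 16
  past16 <- coh$subjects$subject_id[coh$subjects$end_age > 16.5]
  with16 <- unique(coh$visits$subject_id[coh$visits$age_years > 16])
  expect_gt(mean(past16 %in% with16), 0.99)
})

test_that("synthetic LMS tables are valid and self-consistent", {
  refs <- synthetic_reference_set()
  tab <- refs$reference[["height.male"]]
  expect_true(all(diff(tab$M) > 0))
  expect_true(all(tab$S > 0))
  # monotone-median violation is rejected
  expect_error(synthetic_lms_table(function(t) 100 - t, seq(60, 228, 12)),
               "increasing")
  # z-scores of heights simulated under this reference are standard normal
  set.seed(21)
  n <- 1000
  ref <- reference_mean_sd(12, "female", "height", refs)
  x <- stats::rnorm(n, ref$mean, ref$sd)
  z <- lms_zscore(x, 12, "female", "height", refs)$z
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  expect_gt(stats::var(z), 0.8)
  expect_lt(stats::var(z), 1.2)
})

test_that("cohort CSV export round-trips through the pipeline schema", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(synthetic_config(n_subjects = 10), seed = 2)
  paths <- write_cohort_csvs(coh, dir)
  subj <- utils::read.csv(file.path(dir, "subjects.csv"))
  vis <- utils::read.csv(file.path(dir, "visits.csv"))
  expect_setequal(subj$subject_id, coh$subjects$subject_id)
  expect_identical(nrow(vis), nrow(coh$visits))
  expect_true(all(c("subject_id", "age_years", "height_cm", "bmi")
                  %in% names(vis)))
})
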