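test_that("the full study run is deterministic and complete", {
  cfg <- study_config(synthetic = synthetic_config(n_subjects = 120),
                      seed = 314)
  d1 <- tempfile("study1_"); d2 <- tempfile("study2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  r1 <- run_study(cfg, d1)
  r2 <- run_study(cfg, d2)
  expected <- c("exclusions.csv", "baseline_summary.csv", "height_at_16.csv",
                "contrasts.csv", "second_stage.csv", "run_log.txt",
                "effects_male.csv", "effects_female.csv",
                "curves_male.csv", "curves_female.csv",
                "fit_male.txt", "fit_female.txt")
  expect_true(all(file.exists(file.path(d1, expected))))
  # byte-identical outputs under the same seed
  for (f in expected)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # ledger conservation propagated to the CSV
  ex <- utils::read.csv(file.path(d1, "exclusions.csv"))
  expect_identical(sum(ex$n[-nrow(ex)]), ex$n[nrow(ex)])
  # curves cover the reporting grid
  cv <- utils::read.csv(file.path(d1, "curves_female.csv"))
  expect_setequal(range(cv$age_years), c(8, 18))
})

test_that("sensitivity toggles reshape the run", {
  base <- synthetic_config(n_subjects = 100)
  # excluding children starting ART after their 8th birthday tightens the
  # age rule and shows up in the ledger
  d <- tempfile("sens_"); on.exit(unlink(d, recursive = TRUE))
  res <- run_study(study_config(synthetic = base, seed = 11,
                                exclude_art_after_8 = TRUE), d)
  led <- res$bundle$exclusions
  expect_match(led$criterion[2], "<8")
  expect_true(all(res$bundle$subjects$art_init_age < 8))
  # Thailand split: one fit per sex and country stratum
  d2 <- tempfile("sens2_"); on.exit(unlink(d2, recursive = TRUE), add = TRUE)
  res2 <- run_study(study_config(
    synthetic = synthetic_config(n_subjects = 150), seed = 12,
    sex = "female", thailand_split = TRUE), d2)
  expect_setequal(names(res2$fits), c("female_thailand", "female_elsewhere"))
})
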