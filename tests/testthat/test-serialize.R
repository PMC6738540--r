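test_that("fit serialization round-trips bit-exactly", {
  fx <- cached_girls_fit()
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_sitar(fx$fit, path)
  back <- read_sitar(path)

  expect_identical(back$beta, fx$fit$beta)
  expect_identical(back$sigma, fx$fit$sigma)
  expect_identical(back$loglik, fx$fit$loglik)
  expect_identical(unname(back$vcov), unname(fx$fit$vcov))
  expect_identical(as.numeric(back$omega), as.numeric(fx$fit$omega))
  expect_identical(back$curve$coef, unname(fx$fit$curve$coef))
  expect_identical(back$converged, fx$fit$converged)
  expect_identical(back$n_obs, fx$fit$n_obs)

  # the reloaded model predicts and contrasts identically
  t <- seq(8.5, 17.5, by = 0.25)
  lv <- levels(fx$cohort$subjects$haz_group)
  la <- levels(fx$cohort$subjects$age_group)
  ref <- data.frame(haz_group = factor("normal", lv),
                    age_group = factor("1-2", la))
  sev <- transform(ref, haz_group = factor("severe_stunting", lv))
  expect_identical(predict(back, t, profile = sev),
                   predict(fx$fit, t, profile = sev))
  c1 <- sitar_contrast(fx$fit, "b", sev, ref)
  c2 <- sitar_contrast(back, "b", sev, ref)
  expect_identical(c2$estimate, c1$estimate)
  expect_identical(c2$se, c1$se)

  # a second write of the reloaded fit is byte-identical
  path2 <- tempfile(fileext = ".txt")
  on.exit(unlink(path2), add = TRUE)
  write_sitar(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("foreign files are rejected", {
  p <- tempfile()
  writeLines("something else", p)
  on.exit(unlink(p))
  expect_error(read_sitar(p), "not a growthspurt")
})
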