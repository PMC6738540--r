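test_that("size, timing and intensity transform the curve as defined", {
  cv <- pb_sitar_curve()$curve
  t <- seq(9, 16, by = 0.5)
  # zero effects return the population curve
  expect_equal(sitar_mean(cv, 0, 0, 0, t), curve_eval(cv, t))
  # size shifts every age equally
  expect_equal(sitar_mean(cv, 3, 0, 0, t), curve_eval(cv, t) + 3)
  # time-compression identity: c = ln 2 reads the c = 0 curve at age 2t
  t2 <- seq(5, 9, by = 0.25)
  expect_equal(sitar_mean(cv, 0, 0, log(2), t2),
               sitar_mean(cv, 0, 0, 0, 2 * t2))
  # timing shifts the whole curve in age
  expect_equal(sitar_mean(cv, 0, 0.7, 0, t), curve_eval(cv, t - 0.7))
})

test_that("velocity is the exact derivative of the distance curve", {
  cv <- pb_sitar_curve()$curve
  t <- seq(9, 16, by = 0.5)
  expect_equal(sitar_velocity(cv, 0, 0, 0, t), curve_eval(cv, t, deriv = 1L))
  # quadrature of velocity recovers height differences for arbitrary
  # (a, b, c)
  for (p in list(c(0, 0, 0), c(4, 0.8, 0.2), c(-2, -1.1, -0.15))) {
    gain <- stats::integrate(function(x)
      sitar_velocity(cv, p[1], p[2], p[3], x), 8, 18,
      rel.tol = 1e-10, abs.tol = 1e-10)$value
    expect_equal(gain,
                 sitar_mean(cv, p[1], p[2], p[3], 18) -
                   sitar_mean(cv, p[1], p[2], p[3], 8),
                 tolerance = 1e-6 / max(1, abs(gain)))
  }
  # peak velocity scales by exp(c)
  g <- seq(9, 15, by = 0.001)
  v0 <- max(sitar_velocity(cv, 0, 0, 0, g))
  v1 <- max(sitar_velocity(cv, 0, 0, log(1.1), g / 1.1))
  expect_equal(v1, 1.1 * v0, tolerance = 1e-6)
})

test_that("age at peak height velocity obeys the closed form", {
  cv <- pb_sitar_curve()$curve
  a0 <- aphv(cv, search_range = c(9, 16))
  # timing shift moves the peak one-for-one
  expect_equal(aphv(cv, b = 0.5, search_range = c(9, 17)), a0 + 0.5,
               tolerance = 1e-5)
  # compression halves the peak age
  expect_equal(aphv(cv, c = log(2), search_range = c(4, 9)), a0 / 2,
               tolerance = 1e-5)
  # closed form aphv = b + u0 exp(-c) vs golden-section search
  for (b in c(-2, -0.5, 0, 1.2, 2)) {
    for (cc in c(-0.5, -0.1, 0, 0.25, 0.5)) {
      got <- aphv(cv, b = b, c = cc, search_range = c(4.5, 22))
      expect_lt(abs(as.numeric(got) - (b + a0 * exp(-cc))), 1e-4)
    }
  }
  # dense-grid argmax agrees with the optimizer
  g <- seq(9, 16, by = 1e-4)
  expect_lt(abs(as.numeric(a0) - g[which.max(sitar_velocity(cv, 0, 0, 0, g))]),
            1e-4)
})

test_that("a boundary maximum is flagged", {
  cv <- pb_sitar_curve()$curve
  expect_warning(res <- aphv(cv, search_range = c(13, 16)), "boundary")
  expect_true(isTRUE(attr(res, "boundary")))
})
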