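test_that("df columns and df - 1 interior knots at age quantiles", {
  set.seed(2)
  ages <- stats::runif(500, 8, 18)
  b <- ncs_basis(ages, df = 6)
  expect_identical(ncol(b$basis), 6L)
  expect_length(b$knots, 5L)
  expect_equal(b$knots,
               unname(stats::quantile(ages, seq(0, 1, length.out = 7)[2:6])))
  expect_true(all(b$knots > b$boundary[1] & b$knots < b$boundary[2]))
})

test_that("natural constraint: zero second derivative at and beyond bounds", {
  b <- ncs_basis(seq(8, 18, by = 0.05), df = 6)
  eps <- 1e-6
  pts <- c(8, 8 + eps, 18 - eps, 18, 7, 19.5)
  d2 <- ncs_eval(b, pts, deriv = 2L)
  expect_lt(max(abs(d2)), 1e-6)
})

test_that("spline space matches the truncated-power natural-spline oracle", {
  set.seed(3)
  ages <- stats::runif(300, 8, 18)
  b <- ncs_basis(ages, df = 6)
  knots <- c(b$boundary[1], b$knots, b$boundary[2])
  x <- seq(8, 18, length.out = 200)
  B1 <- cbind(1, ncs_eval(b, x))
  B2 <- tp_natural_basis(x, knots)
  # identical column spaces: each basis projects onto the other without
  # residual
  for (pair in list(list(B1, B2), list(B2, B1))) {
    resid <- pair[[1]] - pair[[2]] %*% qr.coef(qr(pair[[2]]), pair[[1]])
    expect_lt(max(abs(resid)), 1e-8)
  }
  # and evaluation at 20 fresh ages stays inside the oracle's span
  x20 <- seq(8.1, 17.9, length.out = 20)
  fitd <- qr.coef(qr(B2), B1)
  expect_lt(max(abs(cbind(1, ncs_eval(b, x20)) -
                      tp_natural_basis(x20, knots) %*% fitd)), 1e-8)
})

test_that("analytic derivative matches central differences", {
  b <- ncs_basis(seq(8, 18, by = 0.1), df = 6)
  x <- seq(8.2, 17.8, length.out = 50)
  h <- 1e-5
  num <- (ncs_eval(b, x + h) - ncs_eval(b, x - h)) / (2 * h)
  expect_lt(max(abs(ncs_eval(b, x, deriv = 1L) - num)), 1e-6)
})

test_that("linear tails: values continue linearly beyond the boundary", {
  b <- ncs_basis(seq(8, 18, by = 0.1), df = 6)
  v18 <- ncs_eval(b, 18)
  d18 <- ncs_eval(b, 18, deriv = 1L)
  expect_equal(ncs_eval(b, 19.3), v18 + 1.3 * d18, tolerance = 1e-10)
  expect_equal(ncs_eval(b, 19.3, deriv = 1L), d18, tolerance = 1e-10)
})

test_that("degenerate inputs raise rank/validation errors", {
  expect_error(ncs_basis(c(8, 9, 10), df = 6), "distinct ages")
  expect_error(ncs_basis(seq(8, 18, 0.1), df = 2), "at least 3")
})
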