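test_that("LMS tables load, sort and validate", {
  d <- data.frame(age_months = c(84, 60, 72), L = 1,
                  M = c(122, 110, 116), S = 0.04)
  tab <- load_lms_table(d, "height", "male")
  expect_s3_class(tab, "lms_table")
  expect_equal(tab$age_months, c(60, 72, 84))
  expect_identical(attr(tab, "measure"), "height")

  expect_error(load_lms_table(rbind(d, d[2, ]), "height", "male"),
               "duplicate")
  expect_error(load_lms_table(transform(d, M = c(122, -1, 116)),
                              "height", "male"), "positive")
  expect_error(load_lms_table(transform(d, S = 0), "height", "male"),
               "positive")
  expect_error(load_lms_table(d[1, ], "height", "male"), "2 rows")
  expect_error(load_lms_table(d[, -1], "height", "male"), "format")
})

test_that("z-scores follow the LMS transform on both branches", {
  refs <- flat_refs()
  # L = 1: z reduces to (x - M) / (M S)
  expect_equal(lms_zscore(105, 3, "male", "height", refs)$z, 1.0)
  # median maps to zero at any covered age
  for (age in c(0.5, 3, 4.99, 5, 12, 18))
    expect_equal(lms_zscore(100, age, "female", "height", refs)$z, 0)
  # L = 0 branch: x = M exp(S) gives z = 1
  refs0 <- flat_refs(L = 0)
  expect_equal(lms_zscore(100 * exp(0.05), 9, "male", "height", refs0)$z, 1.0)
})

test_that("standard/reference switch is half-open at age 5", {
  refs <- flat_refs()
  z <- lms_zscore(c(100, 100), c(5 - 1e-9, 5), "male", "height", refs)
  expect_identical(z$source, c("standard", "reference"))
})

test_that("inverse transform is exact and guards its domain", {
  refs <- flat_refs()
  expect_equal(lms_inverse(0, 7, "male", "height", refs), 100)
  expect_equal(lms_inverse(1, 7, "male", "height", refs), 105)
  # z so negative that (1 + L S z) <= 0 cannot be a measurement
  expect_error(lms_inverse(-25, 7, "male", "height", refs), "domain")
})

test_that("roundtrip identity holds to 1e-9 over random draws", {
  refs <- synthetic_reference_set()
  set.seed(11)
  n <- 1000
  z <- stats::runif(n, -4, 4)
  age <- stats::runif(n, 0.5, 18.5)
  sex <- sample(c("male", "female"), n, TRUE)
  for (measure in c("height", "bmi")) {
    x <- lms_inverse(z, age, sex, measure, refs)
    z2 <- lms_zscore(x, age, sex, measure, refs)$z
    expect_lt(max(abs(z2 - z)), 1e-9)
  }
})

test_that("z-score is strictly increasing in the measurement", {
  refs <- synthetic_reference_set()
  x <- seq(120, 180, by = 0.5)
  for (sex in c("male", "female")) {
    z <- lms_zscore(x, 12, sex, "height", refs)$z
    expect_true(all(diff(z) > 0))
  }
  # skewed BMI branch too
  z <- lms_zscore(seq(12, 30, by = 0.1), 12, "male", "bmi", refs)$z
  expect_true(all(diff(z) > 0))
})

test_that("interpolated L/M/S reproduce stored rows at exact table ages", {
  refs <- synthetic_reference_set()
  tab <- refs$reference[["height.female"]]
  idx <- c(1, 25, nrow(tab))
  for (i in idx) {
    got <- reference_mean_sd(tab$age_months[i] / 12, "female", "height", refs)
    expect_equal(got$mean, tab$M[i])
  }
})

test_that("reference mean/SD agree with the closed form for L = 1", {
  refs <- flat_refs()
  got <- reference_mean_sd(10, "male", "height", refs)
  expect_equal(got$mean, 100)
  expect_equal(got$sd, 5)  # M * S when L = 1
  # symmetric by construction: +1/-1 z equidistant from the median
  hi <- lms_inverse(1, 10, "male", "height", refs)
  lo <- lms_inverse(-1, 10, "male", "height", refs)
  expect_equal(hi - 100, 100 - lo)
})

test_that("ages outside coverage raise a range error", {
  refs <- flat_refs()
  expect_error(lms_zscore(100, 19.5, "male", "height", refs), "coverage")
  expect_error(reference_mean_sd(25, "male", "height", refs), "coverage")
})

test_that("stunting categories use half-open WHO boundaries", {
  expect_identical(as.character(classify_haz(-3.01)), "severe_stunting")
  expect_identical(as.character(classify_haz(-3)), "stunting")
  expect_identical(as.character(classify_haz(-2)), "low_normal")
  expect_identical(as.character(classify_haz(-1)), "normal")
  expect_identical(as.character(classify_haz(-1 - 1e-12)), "low_normal")
})

test_that("BMI categories close the normal band at +1 and open above", {
  expect_identical(as.character(classify_zbmi(-2.5)), "underweight")
  expect_identical(as.character(classify_zbmi(-2)), "normal")
  expect_identical(as.character(classify_zbmi(1)), "normal")
  expect_identical(as.character(classify_zbmi(1 + 1e-12)), "overweight")
  expect_identical(as.character(classify_zbmi(2)), "overweight")
  expect_identical(as.character(classify_zbmi(2.01)), "obese")
})

test_that("both classifiers partition every finite z exactly once", {
  set.seed(4)
  z <- c(stats::rnorm(500, 0, 2), -3, -2, -1, 1, 2)
  for (f in list(classify_haz, classify_zbmi)) {
    cats <- f(z)
    expect_false(anyNA(cats))
    expect_identical(sum(table(cats)), length(z))
  }
})
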