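#' Load an LMS growth-reference table
#'
#' Reads an age-indexed LMS table (columns `age_months`, `L`, `M`, `S`) for a
#' single sex and measure. The LMS representation summarises the reference
#' distribution at each age by a Box-Cox skewness power (L), the median (M,
#' in measure units) and a coefficient of variation (S); z-scores follow from
#' these three curves.
#'
#' @param source a file path or a data frame with columns
#'   `age_months`, `L`, `M`, `S`.
#' @param measure `"height"` or `"bmi"`.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `lms_table`: a data frame sorted by age with
#'   attributes `measure` and `sex`.
#' @examples
#' tab <- load_lms_table(data.frame(age_months = c(60, 72, 84),
#'                                  L = 1, M = c(110, 116, 122), S = 0.04),
#'                       "height", "male")
#' @export
load_lms_table <- function(source, measure = c("height", "bmi"),
                           sex = c("male", "female")) {
  measure <- match.arg(measure)
  sex <- match.arg(sex)
  d <- if (is.character(source)) utils::read.csv(source) else as.data.frame(source)
  need <- c("age_months", "L", "M", "S")
  if (!all(need %in% names(d)))
    stop("LMS table format error: need columns ", paste(need, collapse = ", "))
  d <- d[, need]
  if (!all(vapply(d, is.numeric, TRUE)))
    stop("LMS table format error: all columns must be numeric")
  if (anyNA(d)) stop("LMS table format error: missing values")
  if (anyDuplicated(d$age_months))
    stop("LMS table format error: duplicate age_months rows")
  d <- d[order(d$age_months), , drop = FALSE]
  rownames(d) <- NULL
  if (nrow(d) < 2L) stop("LMS table validation error: need at least 2 rows")
  if (any(d$M <= 0) || any(d$S <= 0))
    stop("LMS table validation error: M and S must be positive")
  structure(d, class = c("lms_table", "data.frame"),
            measure = measure, sex = sex)
}

#' Bundle LMS tables into a reference set
#'
#' Anthropometric practice scores children against a growth *standard* below
#' age 5 and a growth *reference* from age 5 up (the convention used with the
#' WHO Growth Standard and the WHO 2007 reference). A reference set holds
#' both table collections and the switch age; ages strictly below
#' `switch_age` use the standard, ages at or above it the reference.
#'
#' @param standard,reference lists of `lms_table` objects (one per
#'   sex/measure combination used).
#' @param switch_age age in years at which scoring switches collections.
#' @return object of class `lms_reference_set`.
#' @export
lms_reference_set <- function(standard, reference, switch_age = 5) {
  index <- function(tabs) {
    out <- list()
    for (t in tabs) {
      stopifnot(inherits(t, "lms_table"))
      out[[paste(attr(t, "measure"), attr(t, "sex"), sep = ".")]] <- t
    }
    out
  }
  structure(list(standard = index(standard), reference = index(reference),
                 switch_age = switch_age),
            class = "lms_reference_set")
}

# linear interpolation of L, M, S in age (months); errors outside coverage
.lms_at <- function(tab, age_months) {
  rng <- range(tab$age_months)
  if (any(age_months < rng[1] - 1e-9 | age_months > rng[2] + 1e-9))
    stop("age range error: ", paste(round(age_months[
      age_months < rng[1] - 1e-9 | age_months > rng[2] + 1e-9], 2),
      collapse = ", "), " months outside reference coverage [",
      rng[1], ", ", rng[2], "]")
  list(L = stats::approx(tab$age_months, tab$L, age_months, rule = 1)$y,
       M = stats::approx(tab$age_months, tab$M, age_months, rule = 1)$y,
       S = stats::approx(tab$age_months, tab$S, age_months, rule = 1)$y)
}

.pick_table <- function(refs, age_years, measure, sex) {
  stopifnot(inherits(refs, "lms_reference_set"))
  src <- ifelse(age_years < refs$switch_age, "standard", "reference")
  for (k in unique(paste(src, measure, sex, sep = "."))) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    if (is.null(refs[[parts[1L]]][[paste(parts[2L], parts[3L], sep = ".")]]))
      stop("reference set has no ", parts[1L], " table for ", parts[2L],
           ".", parts[3L])
  }
  src
}

#' LMS z-score
#'
#' Converts a measurement to a z-score against the reference distribution at
#' the child's age and sex, using the LMS transform
#' `z = ((x/M)^L - 1) / (L * S)` for `L != 0` and `z = log(x/M) / S` for
#' `L == 0`, with L, M and S linearly interpolated in age.
#'
#' @param x measurement (cm for height, kg/m^2 for BMI); positive.
#' @param age_years decimal age in years.
#' @param sex `"male"` or `"female"` (recycled).
#' @param measure `"height"` or `"bmi"`.
#' @param refs an [lms_reference_set()].
#' @return data frame of class `zscore_result` with columns `z`, `source`
#'   (`"standard"` or `"reference"`) and `age_years`.
#' @export
lms_zscore <- function(x, age_years, sex, measure, refs) {
  stopifnot(all(x > 0), length(age_years) %in% c(1L, length(x)))
  n <- max(length(x), length(age_years))
  x <- rep_len(x, n); age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n)
  src <- .pick_table(refs, age_years, measure, sex)
  z <- numeric(n)
  for (grp in split(seq_len(n), list(src, sex), drop = TRUE)) {
    tab <- refs[[src[grp[1]]]][[paste(measure, sex[grp[1]], sep = ".")]]
    p <- .lms_at(tab, age_years[grp] * 12)
    z[grp] <- ifelse(abs(p$L) > 1e-12,
                     ((x[grp] / p$M)^p$L - 1) / (p$L * p$S),
                     log(x[grp] / p$M) / p$S)
  }
  structure(data.frame(z = z, source = src, age_years = age_years),
            class = c("zscore_result", "data.frame"))
}

#' Inverse LMS transform
#'
#' Maps a z-score back to measurement units at a given age and sex; the exact
#' inverse of [lms_zscore()].
#'
#' @inheritParams lms_zscore
#' @param z z-score(s).
#' @return numeric vector of measurements.
#' @export
lms_inverse <- function(z, age_years, sex, measure, refs) {
  n <- max(length(z), length(age_years))
  z <- rep_len(z, n); age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n)
  src <- .pick_table(refs, age_years, measure, sex)
  x <- numeric(n)
  for (grp in split(seq_len(n), list(src, sex), drop = TRUE)) {
    tab <- refs[[src[grp[1]]]][[paste(measure, sex[grp[1]], sep = ".")]]
    p <- .lms_at(tab, age_years[grp] * 12)
    base <- 1 + p$L * p$S * z[grp]
    bad <- abs(p$L) > 1e-12 & base <= 0
    if (any(bad))
      stop("domain error: z of ", paste(z[grp][bad], collapse = ", "),
           " implies a nonpositive measurement")
    x[grp] <- ifelse(abs(p$L) > 1e-12, p$M * base^(1 / p$L),
                     p$M * exp(p$S * z[grp]))
  }
  x
}

#' Reference mean and SD at an age
#'
#' The reference mean is the median curve M(age); the SD is defined as half
#' the distance between the measurements at z = +1 and z = -1, which equals
#' `M * S` when L = 1 and remains correct for skewed references.
#'
#' @inheritParams lms_zscore
#' @return named list with `mean` and `sd` (measure units).
#' @export
reference_mean_sd <- function(age_years, sex, measure, refs) {
  src <- .pick_table(refs, age_years, measure, sex)
  tab <- refs[[src[1]]][[paste(measure, sex[1], sep = ".")]]
  p <- .lms_at(tab, age_years * 12)
  hi <- lms_inverse(1, age_years, sex, measure, refs)
  lo <- lms_inverse(-1, age_years, sex, measure, refs)
  list(mean = p$M, sd = (hi - lo) / 2)
}

#' WHO height-for-age (stunting) categories
#'
#' Categories follow the WHO cut-offs with lower bounds inclusive:
#' z < -3 severe stunting; -3 <= z < -2 stunting; -2 <= z < -1 low-normal;
#' z >= -1 normal.
#'
#' @param z finite height-for-age z-scores.
#' @return factor with levels `severe_stunting`, `stunting`, `low_normal`,
#'   `normal`.
#' @export
classify_haz <- function(z) {
  stopifnot(all(is.finite(z)))
  cut(z, breaks = c(-Inf, -3, -2, -1, Inf), right = FALSE,
      labels = c("severe_stunting", "stunting", "low_normal", "normal"))
}

#' WHO BMI-for-age categories
#'
#' z < -2 underweight; -2 <= z <= 1 normal; 1 < z <= 2 overweight;
#' z > 2 obese.
#'
#' @param z finite BMI-for-age z-scores.
#' @return factor with levels `underweight`, `normal`, `overweight`, `obese`.
#' @export
classify_zbmi <- function(z) {
  stopifnot(all(is.finite(z)))
  lev <- c("underweight", "normal", "overweight", "obese")
  factor(ifelse(z < -2, "underweight",
         ifelse(z <= 1, "normal",
         ifelse(z <= 2, "overweight", "obese"))), levels = lev)
}

#' Score a visits table against a reference set
#'
#' Adds height-for-age and (where BMI is present) BMI-for-age z-scores and
#' WHO categories to a visits table.
#'
#' @param visits data frame with `subject_id`, `age_years`, `height_cm` and
#'   optionally `bmi`.
#' @param subjects data frame with `subject_id` and `sex`.
#' @param refs an [lms_reference_set()].
#' @return `visits` with columns `haz`, `haz_category` and, if BMI present,
#'   `zbmi`, `zbmi_category` appended.
#' @export
score_visits <- function(visits, subjects, refs) {
  sex <- subjects$sex[match(visits$subject_id, subjects$subject_id)]
  if (anyNA(sex)) stop("visits reference subjects absent from subjects table")
  visits$haz <- lms_zscore(visits$height_cm, visits$age_years, sex,
                           "height", refs)$z
  visits$haz_category <- classify_haz(visits$haz)
  if (!is.null(visits$bmi) && !all(is.na(visits$bmi))) {
    ok <- !is.na(visits$bmi)
    visits$zbmi <- NA_real_
    visits$zbmi[ok] <- lms_zscore(visits$bmi[ok], visits$age_years[ok],
                                  sex[ok], "bmi", refs)$z
    visits$zbmi_category <- factor(NA, levels = levels(classify_zbmi(0)))
    visits$zbmi_category[ok] <- classify_zbmi(visits$zbmi[ok])
  }
  visits
}
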