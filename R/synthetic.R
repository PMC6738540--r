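#' Preece-Baines model 1 growth curve
#'
#' Five-parameter parametric height curve with a single pubertal velocity
#' peak, used as the generating ("true") mean curve for synthetic cohorts.
#' Using a parametric curve rather than a spline keeps the generator
#' independent of the estimator's own basis:
#' `h(t) = h1 - 2 (h1 - h_theta) / (exp(s0 (t - theta)) + exp(s1 (t - theta)))`.
#'
#' @param adult_height adult height asymptote h1 (cm).
#' @param height_at_theta height at age `theta` (cm), below `adult_height`.
#' @param s0,s1 rate constants (per year), `0 < s0 < s1`.
#' @param theta spurt-timing parameter (years), in (9, 16).
#' @return object of class `pb1_curve` with fields and closures `height(t)`
#'   and `velocity(t)` (analytic derivative).
#' @examples
#' crv <- pb1_curve(176.8, 163.0, 0.11, 1.2, 13.9)
#' crv$height(16)
#' @export
pb1_curve <- function(adult_height, height_at_theta, s0, s1, theta) {
  if (!(adult_height > height_at_theta))
    stop("parameter error: adult_height must exceed height_at_theta")
  if (!(s0 > 0 && s1 > s0))
    stop("parameter error: need 0 < s0 < s1")
  if (!(theta > 9 && theta < 16))
    stop("parameter error: theta must lie in (9, 16)")
  d <- adult_height - height_at_theta
  height <- function(t) {
    adult_height - 2 * d / (exp(s0 * (t - theta)) + exp(s1 * (t - theta)))
  }
  velocity <- function(t) {
    e0 <- exp(s0 * (t - theta)); e1 <- exp(s1 * (t - theta))
    2 * d * (s0 * e0 + s1 * e1) / (e0 + e1)^2
  }
  structure(list(adult_height = adult_height,
                 height_at_theta = height_at_theta,
                 s0 = s0, s1 = s1, theta = theta,
                 height = height, velocity = velocity),
            class = "pb1_curve")
}

# default generating curves: plausible boy/girl mean curves with pubertal
# peaks near 13.5 y (boys) and 11.8 y (girls)
default_curve_params <- function() {
  list(male   = list(adult_height = 176.8, height_at_theta = 163.0,
                     s0 = 0.11, s1 = 1.20, theta = 13.9),
       female = list(adult_height = 163.3, height_at_theta = 152.5,
                     s0 = 0.10, s1 = 1.00, theta = 12.3))
}

.pb1_from_params <- function(p) {
  pb1_curve(p$adult_height, p$height_at_theta, p$s0, p$s1, p$theta)
}

#' Build a synthetic LMS table from a median curve
#'
#' Tabulates an LMS reference from a callable median curve: `M(age)` is the
#' curve value, `L` and `S` are supplied profiles (scalars or functions of
#' age in years). For height the median curve must be increasing.
#'
#' @param m_fun function of age in years returning the median measurement.
#' @param ages_months ages (months) at which to tabulate rows.
#' @param L,S skewness power and coefficient of variation; scalar or
#'   function of age in years.
#' @param measure,sex passed to [load_lms_table()].
#' @param check_monotone require `M` strictly increasing (height).
#' @return an `lms_table`.
#' @export
synthetic_lms_table <- function(m_fun, ages_months, L = 1, S = 0.045,
                                measure = "height", sex = "male",
                                check_monotone = measure == "height") {
  yrs <- ages_months / 12
  M <- vapply(yrs, m_fun, numeric(1))
  if (check_monotone && any(diff(M) <= 0))
    stop("parameter error: median curve must be strictly increasing")
  Lv <- if (is.function(L)) vapply(yrs, L, numeric(1)) else rep_len(L, length(yrs))
  Sv <- if (is.function(S)) vapply(yrs, S, numeric(1)) else rep_len(S, length(yrs))
  load_lms_table(data.frame(age_months = ages_months, L = Lv, M = M, S = Sv),
                 measure, sex)
}

#' Synthetic growth-reference set
#'
#' A complete reference set (height and BMI, both sexes, standard below 5 y
#' and reference at 5-19 y) built from the package's generating curves. The
#' height medians are Preece-Baines curves rescaled so that the mean and SD
#' at age 16.0 equal published WHO 2007 summary values (boys 173 cm, SD
#' 7.8; girls 163 cm, SD 6.8). These are synthetic stand-ins for the real
#' WHO tables, which are user-supplied files in production use; they give the
#' z-score engine a realistic, fully reproducible substrate.
#'
#' @param curve_params named list (`male`, `female`) of Preece-Baines
#'   parameter lists; defaults to the package generating curves.
#' @return an [lms_reference_set()].
#' @export
synthetic_reference_set <- function(curve_params = default_curve_params()) {
  anchor <- list(male = c(mean = 173.0, sd = 7.8),
                 female = c(mean = 163.0, sd = 6.8))
  std_months <- seq(0, 60, by = 2)
  ref_months <- seq(60, 228, by = 1)
  standard <- list(); reference <- list()
  for (sex in c("male", "female")) {
    crv <- .pb1_from_params(curve_params[[sex]])
    scale <- anchor[[sex]]["mean"] / crv$height(16)
    m_h <- function(t) unname(scale) * crv$height(t)
    s_h <- unname(anchor[[sex]]["sd"] / anchor[[sex]]["mean"])
    # BMI median: shallow U shape, nadir near 5.5 y; mildly left-skewed
    m_b <- function(t) 15.3 + 0.0275 * (t - 5.5)^2
    standard[[paste0("h", sex)]] <-
      synthetic_lms_table(m_h, std_months, L = 1, S = s_h, "height", sex)
    reference[[paste0("h", sex)]] <-
      synthetic_lms_table(m_h, ref_months, L = 1, S = s_h, "height", sex)
    standard[[paste0("b", sex)]] <-
      synthetic_lms_table(m_b, std_months, L = -1.5, S = 0.09, "bmi", sex)
    reference[[paste0("b", sex)]] <-
      synthetic_lms_table(m_b, ref_months, L = -1.5, S = 0.11, "bmi", sex)
  }
  lms_reference_set(standard, reference, switch_age = 5)
}

#' Load the reference set shipped with the package
#'
#' Reads the synthetic LMS CSV files under `inst/extdata` (written by
#' [write_reference_csvs()]); equivalent to [synthetic_reference_set()] but
#' exercising the file-loading path.
#'
#' @return an [lms_reference_set()].
#' @export
default_reference_set <- function() {
  dir <- system.file("extdata", package = "growthspurt")
  rd <- function(stage, measure, sex)
    load_lms_table(file.path(dir, sprintf("synthetic_lms_%s_%s_%s.csv",
                                          stage, measure, sex)), measure, sex)
  combos <- expand.grid(measure = c("height", "bmi"),
                        sex = c("male", "female"),
                        stringsAsFactors = FALSE)
  lms_reference_set(
    standard  = Map(function(m, s) rd("standard", m, s), combos$measure, combos$sex),
    reference = Map(function(m, s) rd("reference", m, s), combos$measure, combos$sex),
    switch_age = 5)
}

#' Write the synthetic reference tables as CSV files
#'
#' @param dir output directory.
#' @param refs reference set to export; defaults to
#'   [synthetic_reference_set()].
#' @return invisibly, the file paths written.
#' @export
write_reference_csvs <- function(dir, refs = synthetic_reference_set()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (stage in c("standard", "reference")) {
    for (key in names(refs[[stage]])) {
      tab <- refs[[stage]][[key]]
      p <- file.path(dir, sprintf("synthetic_lms_%s_%s_%s.csv", stage,
                                  attr(tab, "measure"), attr(tab, "sex")))
      utils::write.csv(as.data.frame(tab), p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

default_effect_map <- function() {
  rbind(
    data.frame(parameter = "a", covariate = "haz_group",
               level = c("severe_stunting", "stunting", "low_normal"),
               effect = c(-12, -8, -4)),
    data.frame(parameter = "a", covariate = "country_group",
               level = "thailand", effect = -3),
    data.frame(parameter = "b", covariate = "haz_group",
               level = c("severe_stunting", "stunting", "low_normal"),
               effect = c(1.5, 0.8, 0.4)),
    data.frame(parameter = "b", covariate = "age_group",
               level = c("3-5", "6-10"), effect = c(0.2, 0.41)),
    data.frame(parameter = "c", covariate = "haz_group",
               level = "severe_stunting", effect = 0.03))
}

default_omega <- function() {
  o <- diag(c(25, 0.64, 0.01))
  o[1, 2] <- o[2, 1] <- 0.2 * sqrt(25 * 0.64)  # mild positive size-timing corr
  dimnames(o) <- list(c("a", "b", "c"), c("a", "b", "c"))
  o
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of a pooled paediatric HIV cohort starting
#' ART at ages 1-10: covariate marginals close to the published cohort mix,
#' visit spacing with mean about 2.8 months, follow-up into adolescence with
#' transfer/loss censoring before the 19th birthday, and covariate-driven
#' growth-spurt delays up to 1.5 years for the most stunted group.
#'
#' @param n_subjects cohort size.
#' @param sex_ratio_male proportion male.
#' @param age_band_probs sampling probabilities of the ART-initiation age
#'   bands 1-2, 3-5 and 6-10 years.
#' @param haz_group_probs sampling probabilities of the baseline
#'   height-for-age groups.
#' @param country_probs,born_abroad_rate,nnrti_rate,immune_class_probs,art_year_probs
#'   covariate marginals.
#' @param viral_load_mean,viral_load_sd log10 viral-load distribution.
#' @param effect_map data frame (`parameter`, `covariate`, `level`,
#'   `effect`) of additive true fixed effects on the size (a, cm), timing
#'   (b, years) and intensity (c, log-rate) parameters.
#' @param omega 3x3 covariance of the subject-level random effects.
#' @param sigma residual (measurement) SD in cm.
#' @param visit_interval_mean,visit_jitter visit spacing mean and SD (years).
#' @param transfer_rate,transfer_age_range,ltfu_rate,ltfu_age_range,death_rate
#'   censoring process.
#' @param curve_params generating Preece-Baines parameters per sex.
#' @param seed default RNG seed used by [simulate_cohort()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 500,
                             sex_ratio_male = 0.48,
                             age_band_probs = c("1-2" = 0.26, "3-5" = 0.22, "6-10" = 0.52),
                             haz_group_probs = c(severe_stunting = 0.14, stunting = 0.17,
                                                 low_normal = 0.25, normal = 0.44),
                             country_probs = c(thailand = 0.32, uk_ireland = 0.47, other = 0.21),
                             born_abroad_rate = 0.35,
                             nnrti_rate = 0.80,
                             immune_class_probs = c(none = 0.16, mild = 0.11,
                                                    advanced = 0.13, severe = 0.60),
                             art_year_probs = c("<2004" = 0.40, "2004-2007" = 0.40,
                                                ">=2008" = 0.20),
                             viral_load_mean = 5.0, viral_load_sd = 0.7,
                             effect_map = default_effect_map(),
                             omega = default_omega(),
                             sigma = 0.7,
                             visit_interval_mean = 2.8 / 12,
                             visit_jitter = 0.8 / 12,
                             transfer_rate = 0.35, transfer_age_range = c(16, 19),
                             ltfu_rate = 0.08, ltfu_age_range = c(10, 19),
                             death_rate = 0.01,
                             curve_params = default_curve_params(),
                             seed = 20260927L) {
  cfg <- as.list(environment())
  for (nm in c("age_band_probs", "haz_group_probs", "country_probs",
               "immune_class_probs", "art_year_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("config error: ", nm, " must be nonnegative and sum to 1")
  }
  ev <- eigen(cfg$omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("config error: omega must be positive semi-definite")
  if (cfg$sigma < 0) stop("config error: sigma must be nonnegative")
  structure(cfg, class = "synthetic_config")
}

# additive fixed-effect means implied by effect_map for one covariate row
.effect_means <- function(effect_map, covrow) {
  out <- c(a = 0, b = 0, c = 0)
  if (is.null(effect_map) || nrow(effect_map) == 0) return(out)
  for (i in seq_len(nrow(effect_map))) {
    v <- as.character(covrow[[effect_map$covariate[i]]])
    if (!is.na(v) && v == effect_map$level[i])
      out[effect_map$parameter[i]] <- out[effect_map$parameter[i]] +
        effect_map$effect[i]
  }
  out
}

#' Simulate a synthetic longitudinal cohort
#'
#' Samples covariates, draws subject-level size/timing/intensity effects from
#' `effect_map` plus multivariate-normal deviations, schedules visits from
#' ART initiation to the censoring age, and measures heights from the
#' shape-invariant transform of the generating curve plus Gaussian noise.
#' All randomness flows from one seeded stream, so outputs are byte-identical
#' given `(config, seed)`.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list of class `synthetic_cohort` with `subjects`, `visits` and
#'   `truth` (per-subject true effects, the effect map, omega, sigma, curve
#'   parameters and seed).
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio_male, "male", "female")
  age_group <- sample(names(config$age_band_probs), n, TRUE, config$age_band_probs)
  art_init_age <- c("1-2" = NA)[0]
  lo <- c("1-2" = 1, "3-5" = 3, "6-10" = 6)[age_group]
  hi <- c("1-2" = 3, "3-5" = 6, "6-10" = 11)[age_group]
  art_init_age <- stats::runif(n, lo, hi)
  haz_group <- factor(sample(names(config$haz_group_probs), n, TRUE,
                             config$haz_group_probs),
                      levels = names(config$haz_group_probs))
  country_group <- sample(names(config$country_probs), n, TRUE, config$country_probs)
  born_abroad <- stats::runif(n) < config$born_abroad_rate
  regimen <- ifelse(stats::runif(n) < config$nnrti_rate, "nnrti", "bpi")
  who_immune_class <- sample(names(config$immune_class_probs), n, TRUE,
                             config$immune_class_probs)
  period <- sample(names(config$art_year_probs), n, TRUE, config$art_year_probs)
  art_init_year <- ifelse(period == "<2004", sample(1998:2003, n, TRUE),
                   ifelse(period == "2004-2007", sample(2004:2007, n, TRUE),
                          sample(2008:2015, n, TRUE)))
  viral_load_log10 <- stats::rnorm(n, config$viral_load_mean, config$viral_load_sd)

  # censoring: earliest of 19th birthday, transfer, loss to follow-up, death
  end_age <- rep(19, n); end_reason <- rep("in_care", n)
  tr <- stats::runif(n) < config$transfer_rate
  tr_age <- stats::runif(n, config$transfer_age_range[1], config$transfer_age_range[2])
  lt <- stats::runif(n) < config$ltfu_rate
  lt_age <- stats::runif(n, config$ltfu_age_range[1], config$ltfu_age_range[2])
  de <- stats::runif(n) < config$death_rate
  de_age <- stats::runif(n, pmax(art_init_age + 0.5, 9), 19)
  for (i in seq_len(n)) {
    cand <- c(in_care = 19,
              transfer = if (tr[i]) tr_age[i] else Inf,
              ltfu = if (lt[i]) lt_age[i] else Inf,
              death = if (de[i]) de_age[i] else Inf)
    end_reason[i] <- names(cand)[which.min(cand)]
    end_age[i] <- max(min(cand), art_init_age[i] + 0.6)
  }

  subjects <- data.frame(
    subject_id = ids, sex = sex, country_group = country_group,
    born_abroad = born_abroad, art_init_age = art_init_age,
    art_init_year = art_init_year, regimen = regimen,
    viral_load_log10 = viral_load_log10, who_immune_class = who_immune_class,
    acquisition = "vertical", end_age = end_age, end_reason = end_reason,
    age_group = factor(age_group, levels = names(config$age_band_probs)),
    haz_group = haz_group, stringsAsFactors = FALSE)

  mu <- t(vapply(seq_len(n), function(i)
    .effect_means(config$effect_map, subjects[i, ]), numeric(3)))
  re <- matrix(stats::rnorm(3 * n), n, 3)
  ch <- tryCatch(chol(config$omega), error = function(e) {
    ev <- eigen(config$omega, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  })
  re <- re %*% ch
  eff <- mu + re

  curves <- lapply(config$curve_params, .pb1_from_params)
  zb <- stats::rnorm(n, -0.1, 0.9)  # stable subject-level BMI z offset
  bmi_m <- function(t) 15.3 + 0.0275 * (t - 5.5)^2

  vis <- vector("list", n)
  for (i in seq_len(n)) {
    t <- art_init_age[i]
    times <- numeric(0)
    while (t <= min(end_age[i], 19)) {
      times <- c(times, t)
      t <- t + max(1 / 52, stats::rnorm(1, config$visit_interval_mean,
                                        config$visit_jitter))
    }
    crv <- curves[[sex[i]]]
    a <- mu[i, 1] + re[i, 1]; b <- mu[i, 2] + re[i, 2]; cc <- mu[i, 3] + re[i, 3]
    h <- a + crv$height((times - b) * exp(cc)) +
      stats::rnorm(length(times), 0, config$sigma)
    bmi <- bmi_m(times) * (1 + 0.1 * (zb[i] + stats::rnorm(length(times), 0, 0.15)))
    vis[[i]] <- data.frame(subject_id = ids[i], age_years = times,
                           height_cm = h, bmi = bmi, stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, vis)
  rownames(visits) <- NULL

  truth <- list(
    effects = data.frame(subject_id = ids,
                         a_true = eff[, 1], b_true = eff[, 2], c_true = eff[, 3],
                         a_mean = mu[, 1], b_mean = mu[, 2], c_mean = mu[, 3],
                         stringsAsFactors = FALSE),
    effect_map = config$effect_map, omega = config$omega, sigma = config$sigma,
    curve_params = config$curve_params, seed = seed)
  structure(list(subjects = subjects, visits = visits, truth = truth),
            class = "synthetic_cohort")
}

#' Export a synthetic cohort as CSV files
#'
#' Writes `subjects.csv`, `visits.csv` and `truth.csv` matching the pipeline
#' input schema.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("subjects.csv", "visits.csv", "truth.csv"))
  utils::write.csv(cohort$subjects, p[1], row.names = FALSE)
  utils::write.csv(cohort$visits, p[2], row.names = FALSE)
  utils::write.csv(cohort$truth$effects, p[3], row.names = FALSE)
  invisible(p)
}
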