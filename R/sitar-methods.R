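#' Evaluate a SITAR mean curve for given subject parameters
#'
#' `sitar_mean()` returns heights `a + h((t - b) * exp(c))` for a population
#' curve `h`; `sitar_velocity()` returns the growth velocity
#' `exp(c) * h'((t - b) * exp(c))` (cm/year), which does not depend on `a`.
#'
#' @param curve a `sitar_curve` (e.g. `fit$curve`).
#' @param a,b,c size shift (cm), timing shift (years), intensity (log-rate).
#' @param ages ages (years) at which to evaluate.
#' @return numeric vector of heights (cm) or velocities (cm/year).
#' @export
sitar_mean <- function(curve, a = 0, b = 0, c = 0, ages) {
  stopifnot(inherits(curve, "sitar_curve"))
  a + curve_eval(curve, (ages - b) * exp(c))
}

#' @rdname sitar_mean
#' @export
sitar_velocity <- function(curve, a = 0, b = 0, c = 0, ages) {
  stopifnot(inherits(curve, "sitar_curve"))
  exp(c) * curve_eval(curve, (ages - b) * exp(c), deriv = 1L)
}

#' Age at peak height velocity
#'
#' Finds the age maximising the growth-velocity curve over a search range.
#' For a subject with timing `b` and intensity `c` the maximiser satisfies
#' `aphv = b + u0 * exp(-c)` where `u0` is the population-curve peak, so the
#' numeric search and the closed form agree; the search is used so that the
#' same code serves any curve.
#'
#' @param object a `sitar` fit or a `sitar_curve`.
#' @param b,c timing and intensity parameters of the individual curve.
#' @param search_range length-2 numeric; defaults to the spline boundary
#'   knots.
#' @return age in years, with attribute `boundary = TRUE` (plus a warning)
#'   when the maximum lies on the range boundary.
#' @export
aphv <- function(object, b = 0, c = 0, search_range = NULL) {
  curve <- if (inherits(object, "sitar")) object$curve else object
  stopifnot(inherits(curve, "sitar_curve"))
  if (is.null(search_range)) search_range <- curve$basis$boundary
  v <- function(t) sitar_velocity(curve, 0, b, c, t)
  # coarse grid first: the velocity curve need not be unimodal over a wide
  # range (flat linear tails, pre-pubertal dip), then golden-section refine
  grid <- seq(search_range[1], search_range[2], length.out = 401L)
  i <- which.max(v(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(v, interval = c(lo, hi), maximum = TRUE, tol = 1e-9)
  out <- opt$maximum
  tol <- 1e-3 * diff(search_range)
  if (min(out - search_range[1], search_range[2] - out) < tol) {
    warning("velocity maximum lies on the search-range boundary")
    attr(out, "boundary") <- TRUE
  }
  out
}

#' @export
print.sitar <- function(x, ...) {
  cat("SITAR growth model (natural spline, df =", x$curve$basis$df, ")\n")
  cat(sprintf("  %d observations, %d subjects; logLik %.2f; sigma %.3f cm\n",
              x$n_obs, x$n_subjects, x$loglik, x$sigma))
  cat("  converged:", x$converged, "after", x$iterations, "iterations\n")
  invisible(x)
}

#' @export
summary.sitar <- function(object, ...) {
  fe <- object$beta
  se <- sqrt(diag(object$vcov))
  zval <- fe / se
  tab <- cbind(Estimate = fe, `Std. Error` = se, `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  sd_re <- sqrt(diag(object$omega))
  structure(list(fixed = tab, omega = object$omega, sd_re = sd_re,
                 sigma = object$sigma, loglik = object$loglik,
                 k_params = object$k_params, n_obs = object$n_obs,
                 n_subjects = object$n_subjects,
                 converged = object$converged,
                 iterations = object$iterations),
            class = "summary.sitar")
}

#' @export
print.summary.sitar <- function(x, ...) {
  cat("SITAR growth model\n\nFixed effects:\n")
  stats::printCoefmat(x$fixed, digits = 4)
  cat("\nRandom-effect SDs: a", format(x$sd_re[1], digits = 4), "cm, b",
      format(x$sd_re[2], digits = 4), "y, c",
      format(x$sd_re[3], digits = 4), "\n")
  cat("Residual SD:", format(x$sigma, digits = 4), "cm\n")
  cat(sprintf("logLik %.2f on %d parameters; n = %d obs / %d subjects\n",
              x$loglik, x$k_params, x$n_obs, x$n_subjects))
  invisible(x)
}

#' @export
coef.sitar <- function(object, ...) object$beta

#' @export
logLik.sitar <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.sitar <- function(object, ...) object$n_obs

#' @export
fitted.sitar <- function(object, ...) object$fitted

#' @export
residuals.sitar <- function(object, ...) object$y - object$fitted

# fixed-effect contribution of a covariate profile to one parameter block
.profile_row <- function(fit, parameter, profile) {
  dz <- fit$designs[[parameter]]
  tr <- stats::delete.response(dz$terms)
  X <- tryCatch(
    stats::model.matrix(tr, stats::model.frame(tr, profile,
                                               xlev = dz$xlevels)),
    error = function(e) stop("design error: ", conditionMessage(e)))
  X[1L, , drop = TRUE]
}

#' Predict heights or velocities from a fitted SITAR model
#'
#' @param object a fitted `sitar` model.
#' @param ages ages (years) at which to predict.
#' @param profile optional 1-row data frame of covariates; its fixed effects
#'   on a, b and c are applied. Omitted terms default to the reference
#'   profile.
#' @param a,b,c additional subject-level offsets added on top of the
#'   profile's fixed effects (e.g. a subject's empirical-Bayes effects).
#' @param what `"height"` (cm) or `"velocity"` (cm/year).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.sitar <- function(object, ages, profile = NULL, a = 0, b = 0, c = 0,
                          what = c("height", "velocity"), ...) {
  what <- match.arg(what)
  # reference-profile fixed effects: the a-intercept lives in the curve,
  # the b/c intercepts are applied so that predictions line up with the
  # fitted trajectories
  afix <- 0
  bfix <- if ("(Intercept)" %in% names(object$beta_b))
    unname(object$beta_b["(Intercept)"]) else 0
  cfix <- if ("(Intercept)" %in% names(object$beta_c))
    unname(object$beta_c["(Intercept)"]) else 0
  if (!is.null(profile)) {
    xa <- .profile_row(object, "a", profile)
    afix <- sum(xa * object$beta_a) - unname(object$beta_a[1L])  # minus intercept,
    # which already lives in the curve
    if (length(object$beta_b))
      bfix <- sum(.profile_row(object, "b", profile) * object$beta_b)
    if (length(object$beta_c))
      cfix <- sum(.profile_row(object, "c", profile) * object$beta_c)
  }
  at <- afix + a; bt <- bfix + b; ct <- cfix + c
  tt <- if (object$log_age) log(ages) else ages
  if (what == "height") {
    ht <- sitar_mean(object$curve, at, bt, ct, tt)
    if (object$log_height) exp(ht) else ht
  } else {
    v <- sitar_velocity(object$curve, at, bt, ct, tt)
    if (object$log_age) v <- v / ages          # d(log t)/dt
    if (object$log_height) {
      ht <- sitar_mean(object$curve, at, bt, ct, tt)
      v <- exp(ht) * v                         # dy/dt = y d(log y)/dt
    }
    v
  }
}

#' Per-subject empirical-Bayes growth-spurt effects
#'
#' Returns the posterior-mode (BLUP) size, timing and intensity effects of
#' each subject from the final linearized mixed-model step; these are the
#' inputs to the second-stage regression.
#'
#' @param fit a converged `sitar` fit.
#' @param subject_ids optional subset of subjects to return.
#' @return data frame with columns `subject_id`, `a_i` (cm), `b_i` (years),
#'   `c_i` (log-rate), one row per subject.
#' @export
subject_effects <- function(fit, subject_ids = NULL) {
  stopifnot(inherits(fit, "sitar"))
  out <- fit$ranef
  if (!is.null(subject_ids)) {
    m <- match(as.character(subject_ids), out$subject_id)
    if (anyNA(m))
      stop("key error: subjects absent from fit: ",
           paste(subject_ids[is.na(m)], collapse = ", "))
    out <- out[m, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Wald contrast between two covariate profiles
#'
#' Estimates the difference in the fixed-effect mean of one SITAR parameter
#' between two covariate profiles, `x_A' beta - x_B' beta`, with a Wald
#' standard error from the fixed-effect covariance of the final linearized
#' step and a normal-quantile 95% CI. For the timing parameter a positive
#' estimate means profile A has its growth spurt later than profile B.
#'
#' @param fit a fitted `sitar` model.
#' @param parameter `"a"`, `"b"` or `"c"`.
#' @param profile_a,profile_b 1-row data frames of covariates.
#' @param level confidence level.
#' @return list of class `sitar_contrast` with `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
sitar_contrast <- function(fit, parameter = c("a", "b", "c"),
                           profile_a, profile_b, level = 0.95) {
  stopifnot(inherits(fit, "sitar"))
  parameter <- match.arg(parameter)
  idx <- fit$index[[parameter]]
  if (!length(idx)) stop("no fixed effects on parameter ", parameter)
  d <- .profile_row(fit, parameter, profile_a) -
    .profile_row(fit, parameter, profile_b)
  if (parameter == "a") d <- d[names(fit$beta_a)]
  est <- sum(d * fit$beta[idx])
  se <- sqrt(drop(t(d) %*% fit$vcov[idx, idx, drop = FALSE] %*% d))
  q <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(est / se)) else as.numeric(est == 0)
  structure(list(parameter = parameter, estimate = est, se = se,
                 ci_low = est - q * se, ci_high = est + q * se,
                 p_value = p, level = level),
            class = "sitar_contrast")
}

#' @export
print.sitar_contrast <- function(x, ...) {
  unit <- c(a = "cm", b = "years", c = "log-rate")[x$parameter]
  cat(sprintf("Contrast on %s: %.3f %s (%.0f%% CI %.3f to %.3f), p = %.4g\n",
              x$parameter, x$estimate, unit, 100 * x$level, x$ci_low,
              x$ci_high, x$p_value))
  invisible(x)
}

#' Compare SITAR fits by BIC
#'
#' `BIC` (via the `logLik` method) is `-2 logLik + k log(n_obs)` with `k` the
#' number of estimated parameters (spline coefficients, fixed effects,
#' covariance terms and the residual SD). `compare_models()` returns the
#' index of the fit minimising BIC, breaking ties toward the model with
#' fewer parameters; all fits must share the same observation count.
#'
#' @param ... fitted `sitar` models (or a single list of them).
#' @return integer index of the preferred model, with attribute `bic`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !inherits(fits[[1L]], "sitar"))
    fits <- fits[[1L]]
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "sitar")))
  n <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) != 1L)
    stop("comparison error: fits have different observation counts")
  bic <- vapply(fits, function(f) stats::BIC(logLik(f)), numeric(1))
  k <- vapply(fits, function(f) f$k_params, numeric(1))
  best <- which(bic <= min(bic) + 1e-8)
  best <- best[which.min(k[best])]
  structure(best, bic = bic)
}

#' Plot a fitted SITAR model
#'
#' Draws the population distance curve with the observed measurements in the
#' background and the corresponding velocity curve underneath.
#'
#' @param x a fitted `sitar` model.
#' @param ages age grid; defaults to the observed boundary.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sitar <- function(x, ages = NULL, ...) {
  if (is.null(ages)) {
    b <- x$curve$basis$boundary
    if (x$log_age) b <- exp(b)
    ages <- seq(b[1], b[2], length.out = 101)
  }
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(ages, predict(x, ages), type = "l", lwd = 2,
                 xlab = "age (years)", ylab = "height (cm)",
                 main = "population distance curve", ...)
  graphics::plot(ages, predict(x, ages, what = "velocity"), type = "l",
                 lwd = 2, xlab = "age (years)", ylab = "velocity (cm/year)",
                 main = "population velocity curve", ...)
  invisible(x)
}
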