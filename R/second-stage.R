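#' Second-stage regression of growth-spurt parameters on covariates
#'
#' Regresses the empirical-Bayes size, timing and intensity effects from a
#' SITAR fit on clinical covariates by ordinary least squares, one model per
#' outcome, on complete cases only. Coefficients come with 95% confidence
#' intervals and p-values; optional interaction terms are screened with
#' F-tests against the main-effects model and reported as significant when
#' p < 0.05.
#'
#' @param effects data frame from [subject_effects()] (columns `subject_id`,
#'   `a_i`, `b_i`, `c_i`).
#' @param subjects per-subject covariate table.
#' @param formula right-hand-side formula of covariates; the default mirrors
#'   the usual adjustment set (sex, country group, ART calendar period,
#'   regimen, log viral load, WHO immune class, baseline zBMI when present).
#' @param outcomes which of `a`, `b`, `c` to model.
#' @param interactions character vector of interaction terms to test, e.g.
#'   `c("sex:born_abroad")`.
#' @return list of class `second_stage`: per outcome a list with `terms`
#'   (name, coefficient, ci_low, ci_high, p), `n_used`, `interaction_tests`
#'   and the underlying `lm` fit.
#' @export
second_stage_regression <- function(effects, subjects, formula = NULL,
                                    outcomes = c("a", "b", "c"),
                                    interactions = NULL) {
  if (is.null(formula)) {
    base_vars <- intersect(
      c("sex", "country_group", "art_period", "regimen",
        "viral_load_log10", "who_immune_class", "zbmi_baseline"),
      names(subjects))
    formula <- stats::reformulate(base_vars)
  }
  if (!is.null(subjects$art_init_year) && is.null(subjects$art_period))
    subjects$art_period <- art_period(subjects$art_init_year)
  d <- merge(effects, subjects, by = "subject_id")
  vars <- all.vars(formula)
  if (!is.null(interactions))
    vars <- union(vars, unlist(strsplit(interactions, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(d))
  if (length(miss)) stop("covariates not found: ", paste(miss, collapse = ", "))
  d <- d[stats::complete.cases(d[, vars, drop = FALSE]), , drop = FALSE]
  out <- list()
  for (o in match.arg(outcomes, c("a", "b", "c"), several.ok = TRUE)) {
    f <- stats::update(formula, paste0(o, "_i ~ ."))
    fit <- stats::lm(f, data = d)
    if (anyNA(stats::coef(fit)))
      stop("rank error: aliased terms in the ", o, "-model design: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    ci <- stats::confint(fit)
    sm <- summary(fit)$coefficients
    terms_tab <- data.frame(
      name = rownames(sm), coefficient = sm[, 1],
      ci_low = ci[rownames(sm), 1], ci_high = ci[rownames(sm), 2],
      p = sm[, 4], row.names = NULL)
    itests <- NULL
    if (!is.null(interactions)) {
      itests <- do.call(rbind, lapply(interactions, function(term) {
        f2 <- stats::update(f, paste0(". ~ . + ", term))
        fit2 <- stats::lm(f2, data = d)
        a <- stats::anova(fit, fit2)
        data.frame(name = term, p = a$`Pr(>F)`[2L],
                   retained = a$`Pr(>F)`[2L] < 0.05)
      }))
    }
    out[[o]] <- list(outcome = o, terms = terms_tab, n_used = nrow(d),
                     interaction_tests = itests, fit = fit)
  }
  structure(out, class = "second_stage")
}

#' @export
print.second_stage <- function(x, ...) {
  for (o in names(x)) {
    cat("Outcome", o, sprintf("(n = %d):\n", x[[o]]$n_used))
    print(x[[o]]$terms, digits = 3)
    if (!is.null(x[[o]]$interaction_tests)) {
      cat("  interaction F-tests:\n")
      print(x[[o]]$interaction_tests, digits = 3)
    }
    cat("\n")
  }
  invisible(x)
}

#' ART calendar-year periods
#'
#' Encodes calendar year of ART initiation into the three analysis periods
#' <2004, 2004-2007 and >=2008.
#'
#' @param year integer calendar years.
#' @return factor with levels `<2004`, `2004-2007`, `>=2008`.
#' @export
art_period <- function(year) {
  cut(year, breaks = c(-Inf, 2003.5, 2007.5, Inf),
      labels = c("<2004", "2004-2007", ">=2008"))
}
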