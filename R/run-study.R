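#' Configure an end-to-end growth-spurt study
#'
#' Bundles every switch of the pipeline: the input (paths to `subjects.csv` /
#' `visits.csv`, or a [synthetic_config()] to simulate), the growth
#' reference, the SITAR specification, and the sensitivity toggles (separate
#' fits for Thailand and elsewhere; excluding children starting ART after
#' their 8th birthday; an alternate reference set, e.g. a national
#' reference, supplied as tables).
#'
#' @param synthetic a [synthetic_config()] used when no input paths are
#'   given.
#' @param subjects_file,visits_file optional CSV paths replacing simulation.
#' @param refs an [lms_reference_set()]; defaults to the packaged synthetic
#'   reference (see [default_reference_set()]).
#' @param seed integer seed governing all randomness of a run.
#' @param df spline degrees of freedom.
#' @param design right-hand-side formula applied to the means of a, b and c
#'   (per-parameter overrides via `a_design`, `b_design`, `c_design`).
#' @param a_design,b_design,c_design optional per-parameter designs.
#' @param sex `"both"`, `"male"` or `"female"`.
#' @param drop_implausible drop flagged implausible visits.
#' @param exclude_art_after_8 sensitivity: exclude subjects starting ART at
#'   age 8 or later.
#' @param thailand_split sensitivity: fit Thailand and elsewhere separately.
#' @param interactions interaction terms screened in the second stage.
#' @param grid_step age step (years) of the exported curve grid.
#' @return list of class `study_config`.
#' @export
study_config <- function(synthetic = synthetic_config(),
                         subjects_file = NULL, visits_file = NULL,
                         refs = NULL, seed = 20260927L, df = 6,
                         design = ~ haz_group + age_group,
                         a_design = NULL, b_design = NULL, c_design = NULL,
                         sex = c("both", "male", "female"),
                         drop_implausible = TRUE,
                         exclude_art_after_8 = FALSE,
                         thailand_split = FALSE,
                         interactions = "sex:born_abroad",
                         grid_step = 0.1) {
  sex <- match.arg(sex)
  structure(list(synthetic = synthetic, subjects_file = subjects_file,
                 visits_file = visits_file, refs = refs, seed = seed,
                 df = df, design = design,
                 a_design = if (is.null(a_design)) design else a_design,
                 b_design = if (is.null(b_design)) design else b_design,
                 c_design = if (is.null(c_design)) design else c_design,
                 sex = sex, drop_implausible = drop_implausible,
                 exclude_art_after_8 = exclude_art_after_8,
                 thailand_split = thailand_split,
                 interactions = interactions, grid_step = grid_step),
            class = "study_config")
}

# derive fit covariates from the bundle: measured baseline HAZ group and
# ART-initiation age band
.fit_covariates <- function(bundle) {
  s <- bundle$subjects
  base <- bundle$baseline[match(s$subject_id, bundle$baseline$subject_id), ]
  s$haz_group <- base$haz_category
  s$zbmi_baseline <- base$zbmi
  s$age_group <- cut(s$art_init_age, breaks = c(-Inf, 3, 6, Inf),
                     labels = c("1-2", "3-5", "6-10"))
  # reference levels: normal height, youngest band
  s$haz_group <- stats::relevel(factor(s$haz_group), ref = "normal")
  s
}

.fit_one_stratum <- function(visits, covs, config, label) {
  covs <- droplevels(covs)
  keep <- visits$subject_id %in% covs$subject_id
  fit <- sitar(height_cm ~ age_years | subject_id,
               visits[keep, , drop = FALSE],
               covariates = covs, df = config$df,
               a_formula = config$a_design, b_formula = config$b_design,
               c_formula = config$c_design)
  attr(fit, "stratum") <- label
  fit
}

.default_profiles <- function(covs) {
  covs <- droplevels(covs)
  lh <- levels(covs$haz_group); la <- levels(covs$age_group)
  if (!("normal" %in% lh && "1-2" %in% la)) return(NULL)
  ref <- data.frame(haz_group = factor("normal", lh),
                    age_group = factor("1-2", la))
  list(ref = ref,
       haz = lapply(intersect(c("severe_stunting", "stunting", "low_normal"),
                              lh),
                    function(l) transform(ref, haz_group = factor(l, lh))),
       age = lapply(intersect(c("3-5", "6-10"), la),
                    function(l) transform(ref, age_group = factor(l, la))))
}

#' Run the full study pipeline
#'
#' Simulates or loads a cohort, builds the analysis cohort (eligibility,
#' z-scores, implausibility checks, censoring, baseline), fits sex-stratified
#' SITAR models, extracts subject effects, forms timing contrasts between
#' baseline HAZ and age groups, compares height at 16 against the reference,
#' and runs the second-stage regression. All outputs are written as CSV (and
#' serialized fits) under `out_dir`; a run is deterministic given
#' `config$seed`.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the bundle, fits, effects, contrasts,
#'   height-at-16 table and second-stage results.
#' @export
run_study <- function(config = study_config(), out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  refs <- if (is.null(config$refs)) default_reference_set() else config$refs

  inp <- stage("input", {
    if (!is.null(config$subjects_file)) {
      list(subjects = utils::read.csv(config$subjects_file),
           visits = utils::read.csv(config$visits_file))
    } else {
      coh <- simulate_cohort(config$synthetic, seed = config$seed)
      list(subjects = coh$subjects, visits = coh$visits, truth = coh$truth)
    }
  })

  bundle <- stage("cohort", build_cohort(
    inp$subjects, inp$visits, refs,
    drop_implausible = config$drop_implausible,
    max_art_age = if (config$exclude_art_after_8) 8 else 11))
  utils::write.csv(cbind(data.frame(step = c("input",
                                             bundle$exclusions$criterion,
                                             "final"),
                                    n = c(attr(bundle$exclusions, "n_input"),
                                          -bundle$exclusions$n_excluded,
                                          attr(bundle$exclusions, "n_final")))),
                   file.path(out_dir, "exclusions.csv"), row.names = FALSE)

  summ <- stage("baseline summary", summarize_baseline(bundle))
  utils::write.csv(summ$table, file.path(out_dir, "baseline_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$tests, file.path(out_dir, "baseline_tests.csv"),
                   row.names = FALSE)

  h16 <- stage("height at 16", height_at_16(bundle, refs))
  utils::write.csv(h16, file.path(out_dir, "height_at_16.csv"),
                   row.names = FALSE)

  covs <- stage("covariates", .fit_covariates(bundle))
  sexes <- if (config$sex == "both") c("male", "female") else config$sex
  fits <- list(); all_effects <- list(); contrasts <- list(); curves <- list()
  grid <- seq(8, 18, by = config$grid_step)
  for (s in sexes) {
    cs <- covs[covs$sex == s, , drop = FALSE]
    strata <- if (config$thailand_split)
      list(thailand = cs[cs$country_group == "thailand", , drop = FALSE],
           elsewhere = cs[cs$country_group != "thailand", , drop = FALSE])
    else list(all = cs)
    for (nm in names(strata)) {
      label <- if (nm == "all") s else paste(s, nm, sep = "_")
      fit <- stage(paste("sitar", label),
                   .fit_one_stratum(bundle$visits, strata[[nm]], config, label))
      fits[[label]] <- fit
      write_sitar(fit, file.path(out_dir, paste0("fit_", label, ".txt")))
      eff <- subject_effects(fit)
      utils::write.csv(eff, file.path(out_dir,
                                      paste0("effects_", label, ".csv")),
                       row.names = FALSE)
      all_effects[[label]] <- eff
      prof <- .default_profiles(strata[[nm]])
      cons <- stage(paste("contrasts", label), {
        if (is.null(prof)) NULL else {
        rows <- list()
        for (p in prof$haz) rows[[length(rows) + 1L]] <- data.frame(
          stratum = label, parameter = "b",
          comparison = paste0("haz ", p$haz_group[1], " vs normal"),
          as.data.frame(unclass(sitar_contrast(fit, "b", p, prof$ref))[
            c("estimate", "se", "ci_low", "ci_high", "p_value")]))
        for (p in prof$age) rows[[length(rows) + 1L]] <- data.frame(
          stratum = label, parameter = "b",
          comparison = paste0("age ", p$age_group[1], " vs 1-2"),
          as.data.frame(unclass(sitar_contrast(fit, "b", p, prof$ref))[
            c("estimate", "se", "ci_low", "ci_high", "p_value")]))
        do.call(rbind, rows)
        }
      })
      contrasts[[label]] <- cons
      if (!is.null(prof)) {
        lv <- levels(droplevels(strata[[nm]])$haz_group)
        cv <- do.call(rbind, lapply(lv, function(l) {
          p <- transform(prof$ref, haz_group = factor(l, lv))
          data.frame(stratum = label, haz_group = l, age_years = grid,
                     height_cm = predict(fit, grid, profile = p),
                     velocity_cm_year = predict(fit, grid, profile = p,
                                                what = "velocity"))
        }))
        curves[[label]] <- cv
        utils::write.csv(cv,
                         file.path(out_dir, paste0("curves_", label, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, contrasts),
                   file.path(out_dir, "contrasts.csv"), row.names = FALSE)

  ss <- stage("second stage", {
    eff <- do.call(rbind, all_effects)
    eff <- eff[!duplicated(eff$subject_id), , drop = FALSE]
    covs$art_period <- art_period(covs$art_init_year)
    sub <- covs[covs$subject_id %in% eff$subject_id, , drop = FALSE]
    varies <- function(v) is.numeric(sub[[v]]) ||
      length(unique(stats::na.omit(sub[[v]]))) >= 2L
    cand <- intersect(c("sex", "country_group", "art_period", "regimen",
                        "viral_load_log10", "who_immune_class",
                        "zbmi_baseline"), names(sub))
    cand <- cand[vapply(cand, varies, TRUE)]
    inter <- config$interactions
    if (!is.null(inter)) {
      ok <- vapply(strsplit(inter, ":", fixed = TRUE), function(v)
        all(v %in% names(sub)) && all(vapply(v, varies, TRUE)), TRUE)
      inter <- if (any(ok)) inter[ok] else NULL
    }
    second_stage_regression(eff, sub, stats::reformulate(cand),
                            interactions = inter)
  })
  ss_tab <- do.call(rbind, lapply(ss, function(m)
    cbind(outcome = m$outcome, m$terms, n_used = m$n_used)))
  utils::write.csv(ss_tab, file.path(out_dir, "second_stage.csv"),
                   row.names = FALSE)
  if (!is.null(ss[[1]]$interaction_tests)) {
    it <- do.call(rbind, lapply(ss, function(m)
      cbind(outcome = m$outcome, m$interaction_tests)))
    utils::write.csv(it, file.path(out_dir, "interaction_tests.csv"),
                     row.names = FALSE)
  }

  writeLines(c(paste("growthspurt", as.character(utils::packageVersion("growthspurt"))),
               paste("R", paste(R.version$major, R.version$minor, sep = ".")),
               paste("seed", config$seed),
               paste("subjects", nrow(bundle$subjects)),
               paste("analysis visits", nrow(bundle$visits))),
             file.path(out_dir, "run_log.txt"))

  invisible(list(bundle = bundle, fits = fits, effects = all_effects,
                 contrasts = contrasts, curves = curves, height_at_16 = h16,
                 second_stage = ss, summary = summ,
                 truth = inp$truth, config = config))
}
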