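#' Apply cohort eligibility criteria
#'
#' Applies the study inclusion rules in order, recording attrition at each
#' step: (1) initiated an eligible regimen (NNRTI- or boosted-PI-based);
#' (2) aged 1 to <11 years at ART initiation; (3) not known to have
#' horizontally acquired HIV; (4) aged at least 8 years at the end of
#' follow-up; (5) a height recorded at ART initiation (within the baseline
#' window, 6 months before to 1 month after); (6) a height recorded after
#' age 8.
#'
#' @param subjects subjects table (see [simulate_cohort()] for the schema).
#' @param visits visits table with `subject_id`, `age_years`, `height_cm`.
#' @param baseline_window numeric length 2, allowed offset (years) of the
#'   baseline measurement relative to ART initiation.
#' @param max_art_age exclude subjects initiating at or above this age
#'   (default 11, i.e. "1-10 years old"); the sensitivity analysis dropping
#'   children starting after their 8th birthday passes 8.
#' @return list with `eligible_ids` and `ledger` (class `exclusion_ledger`).
#' @export
apply_inclusion <- function(subjects, visits,
                            baseline_window = c(-0.5, 1 / 12),
                            max_art_age = 11) {
  steps <- list(
    `ineligible ART regimen` = function(s)
      s$regimen %in% c("nnrti", "bpi"),
    age_rule = function(s)
      s$art_init_age >= 1 & s$art_init_age < max_art_age,
    `horizontally acquired HIV` = function(s)
      is.na(s$acquisition) | s$acquisition != "horizontal",
    `aged under 8 at end of follow-up` = function(s)
      s$end_age >= 8,
    `no height recorded at ART initiation` = function(s) {
      off <- visits$age_years -
        s$art_init_age[match(visits$subject_id, s$subject_id)]
      ok <- !is.na(off) & off >= baseline_window[1] & off <= baseline_window[2] &
        !is.na(visits$height_cm)
      s$subject_id %in% visits$subject_id[ok]
    },
    `no height recorded after age 8` = function(s)
      s$subject_id %in%
        visits$subject_id[visits$age_years >= 8 & !is.na(visits$height_cm)])
  names(steps)[2L] <- sprintf("age at ART initiation outside 1 to <%g years",
                              max_art_age)
  n_input <- nrow(subjects)
  ledger <- data.frame(criterion = character(0), n_excluded = integer(0))
  cur <- subjects
  for (nm in names(steps)) {
    keep <- steps[[nm]](cur)
    ledger <- rbind(ledger,
                    data.frame(criterion = nm, n_excluded = sum(!keep)))
    cur <- cur[keep, , drop = FALSE]
  }
  ledger <- structure(ledger, class = c("exclusion_ledger", "data.frame"),
                      n_input = n_input, n_final = nrow(cur))
  list(eligible_ids = cur$subject_id, ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion ledger:", attr(x, "n_input"), "subjects in\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  - %-45s %5d excluded\n", x$criterion[i], x$n_excluded[i]))
  cat(" ", attr(x, "n_final"), "subjects retained\n")
  invisible(x)
}

#' Censor and window visits for growth modelling
#'
#' Keeps measurements between `max(8, art_init_age)` and 18 years, further
#' truncated at each subject's end of follow-up (the earliest of the 19th
#' birthday, transfer to adult care, death or loss to follow-up, as encoded
#' in `end_age`). Idempotent.
#'
#' @param visits visits table.
#' @param subjects subjects table with `art_init_age` and `end_age`.
#' @return the censored visits table.
#' @export
censor_visits <- function(visits, subjects) {
  m <- match(visits$subject_id, subjects$subject_id)
  lo <- pmax(8, subjects$art_init_age[m])
  hi <- pmin(18, subjects$end_age[m], 19)
  out <- visits[!is.na(m) & visits$age_years >= lo & visits$age_years <= hi, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Baseline anthropometry at ART initiation
#'
#' For each subject, selects the scored visit closest to ART initiation
#' within the window 6 months before to 1 month after; ties between a
#' pre-ART and a post-ART visit at equal distance go to the pre-ART visit
#' (untouched by treatment). Returns missing rows for subjects without a
#' qualifying visit.
#'
#' @param visits visits table carrying `haz` (and optionally `zbmi`)
#'   columns, e.g. from [score_visits()].
#' @param subjects subjects table with `art_init_age`.
#' @param window allowed offset range in years.
#' @return data frame with one row per subject: `subject_id`, `offset_years`,
#'   `haz`, `haz_category`, `zbmi`, `zbmi_category`.
#' @export
baseline_anthropometry <- function(visits, subjects,
                                   window = c(-0.5, 1 / 12)) {
  out <- data.frame(subject_id = subjects$subject_id,
                    offset_years = NA_real_, haz = NA_real_,
                    zbmi = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(subjects))) {
    v <- visits[visits$subject_id == subjects$subject_id[i], , drop = FALSE]
    off <- v$age_years - subjects$art_init_age[i]
    ok <- off >= window[1] & off <= window[2]
    if (!any(ok)) next
    v <- v[ok, , drop = FALSE]; off <- off[ok]
    # nearest in absolute offset; tie-break toward the pre-ART visit
    ord <- order(abs(off), off)
    out$offset_years[i] <- off[ord[1L]]
    out$haz[i] <- v$haz[ord[1L]]
    if (!is.null(v$zbmi)) out$zbmi[i] <- v$zbmi[ord[1L]]
  }
  out$haz_category <- factor(NA, levels = levels(classify_haz(0)))
  ok <- !is.na(out$haz)
  out$haz_category[ok] <- classify_haz(out$haz[ok])
  out$zbmi_category <- factor(NA, levels = levels(classify_zbmi(0)))
  ok <- !is.na(out$zbmi)
  out$zbmi_category[ok] <- classify_zbmi(out$zbmi[ok])
  out
}

#' Flag implausible measurement changes
#'
#' Flags a visit when the height drops more than `max_height_drop_cm` since
#' the previous visit, or when the height-for-age z-score changes by more
#' than `max_abs_dhaz` between consecutive visits less than
#' `dhaz_window_years` apart. The thresholds are configurable defaults; the
#' later visit of each offending pair is flagged.
#'
#' @param visits scored visits table (sorted internally by subject and age).
#' @param max_height_drop_cm height-decrease threshold (cm).
#' @param max_abs_dhaz absolute HAZ-change threshold.
#' @param dhaz_window_years the HAZ rule applies to gaps shorter than this.
#' @return data frame `subject_id`, `age_years`, `reason` (possibly empty).
#' @export
flag_implausible <- function(visits, max_height_drop_cm = 2,
                             max_abs_dhaz = 2, dhaz_window_years = 1) {
  visits <- visits[order(visits$subject_id, visits$age_years), , drop = FALSE]
  flags <- list()
  for (sid in unique(visits$subject_id)) {
    v <- visits[visits$subject_id == sid, , drop = FALSE]
    if (nrow(v) < 2L) next
    dh <- diff(v$height_cm)
    dt <- diff(v$age_years)
    dz <- if (!is.null(v$haz)) diff(v$haz) else rep(0, nrow(v) - 1L)
    drop_bad <- dh < -max_height_drop_cm
    haz_bad <- abs(dz) > max_abs_dhaz & dt < dhaz_window_years
    bad <- which(drop_bad | haz_bad)
    if (length(bad))
      flags[[sid]] <- data.frame(
        subject_id = sid, age_years = v$age_years[bad + 1L],
        reason = ifelse(drop_bad[bad] & haz_bad[bad], "height drop; HAZ jump",
                 ifelse(drop_bad[bad], "height drop", "HAZ jump")),
        stringsAsFactors = FALSE)
  }
  if (!length(flags))
    return(data.frame(subject_id = character(0), age_years = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Build an analysis cohort
#'
#' Runs the full cohort-construction sequence: z-scoring of all visits,
#' eligibility with an exclusion ledger, implausible-measurement flags
#' (dropped or kept per `drop_implausible`), censoring to the modelling
#' window, and baseline anthropometry.
#'
#' @param subjects,visits raw input tables.
#' @param refs an [lms_reference_set()].
#' @param drop_implausible drop flagged visits (default) or keep them.
#' @param baseline_window,max_art_age passed to the respective steps.
#' @return list of class `cohort_bundle`: `subjects` (eligible), `visits`
#'   (scored, censored analysis visits), `all_visits` (scored, uncensored),
#'   `baseline`, `exclusions`, `flags`.
#' @export
build_cohort <- function(subjects, visits, refs, drop_implausible = TRUE,
                         baseline_window = c(-0.5, 1 / 12), max_art_age = 11) {
  visits <- score_visits(visits, subjects, refs)
  inc <- apply_inclusion(subjects, visits, baseline_window, max_art_age)
  subj <- subjects[subjects$subject_id %in% inc$eligible_ids, , drop = FALSE]
  vis <- visits[visits$subject_id %in% inc$eligible_ids, , drop = FALSE]
  flags <- flag_implausible(vis)
  if (drop_implausible && nrow(flags)) {
    key <- paste(vis$subject_id, signif(vis$age_years, 12))
    bad <- paste(flags$subject_id, signif(flags$age_years, 12))
    vis <- vis[!(key %in% bad), , drop = FALSE]
  }
  baseline <- baseline_anthropometry(vis, subj, baseline_window)
  analysis <- censor_visits(vis, subj)
  structure(list(subjects = subj, visits = analysis, all_visits = vis,
                 baseline = baseline, exclusions = inc$ledger,
                 flags = flags),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Cohort bundle:", nrow(x$subjects), "subjects,",
      nrow(x$visits), "analysis visits\n")
  print(x$exclusions)
  invisible(x)
}

#' Baseline characteristics stratified by HAZ category
#'
#' Counts (percent) for categorical covariates and median (IQR) for
#' continuous ones, stratified by baseline height-for-age category, with
#' global across-strata tests: chi-square for categorical variables,
#' Kruskal-Wallis for continuous ones.
#'
#' @param bundle a [build_cohort()] result.
#' @param categorical,continuous covariate column names of
#'   `bundle$subjects` to summarise.
#' @return list with `table` (long data frame) and `tests` (variable, p).
#' @export
summarize_baseline <- function(bundle,
                               categorical = c("sex", "country_group",
                                               "born_abroad", "regimen",
                                               "who_immune_class"),
                               continuous = c("art_init_age",
                                              "viral_load_log10")) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  strata <- bundle$baseline$haz_category[
    match(bundle$subjects$subject_id, bundle$baseline$subject_id)]
  rows <- list(); tests <- list()
  for (v in intersect(categorical, names(bundle$subjects))) {
    x <- factor(bundle$subjects[[v]])
    tab <- table(x, strata)
    pct <- 100 * sweep(tab, 2, pmax(colSums(tab), 1L), "/")
    for (l in rownames(tab)) {
      cells <- sprintf("%d (%.0f%%)", tab[l, ], pct[l, ])
      cells[colSums(tab) == 0] <- ""
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = l,
        stat = I(list(stats::setNames(cells, colnames(tab)))))
    }
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    tests[[length(tests) + 1L]] <- data.frame(variable = v, test = "chi-square",
                                              p = p)
  }
  for (v in intersect(continuous, names(bundle$subjects))) {
    x <- bundle$subjects[[v]]
    cells <- vapply(levels(strata), function(s) {
      xs <- x[!is.na(strata) & strata == s]
      if (!length(xs)) return("")
      q <- stats::quantile(xs, c(0.5, 0.25, 0.75), na.rm = TRUE)
      sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3])
    }, "")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "median (IQR)", stat = I(list(cells)))
    p <- tryCatch(stats::kruskal.test(x, strata)$p.value,
                  error = function(e) NA_real_)
    tests[[length(tests) + 1L]] <- data.frame(variable = v,
                                              test = "kruskal-wallis", p = p)
  }
  tab <- do.call(rbind, rows)
  wide <- cbind(tab[, c("variable", "level")],
                do.call(rbind, lapply(tab$stat, function(s)
                  as.data.frame(as.list(s), check.names = FALSE))))
  rownames(wide) <- NULL
  list(table = wide, tests = do.call(rbind, tests))
}

#' Height at age 16 versus the reference
#'
#' For each sex, takes each subject's measurement nearest to the 16th
#' birthday within half a year, summarises mean, SD and n, and runs a
#' one-sample t-test against the reference mean at age 16.
#'
#' @param bundle a [build_cohort()] result (visits need not be censored at
#'   18; the uncensored scored visits are used).
#' @param refs an [lms_reference_set()] covering age 16.
#' @param window half-width (years) of the qualifying window around 16.
#' @return data frame, one row per sex: `sex`, `n`, `mean`, `sd`,
#'   `ref_mean`, `ref_sd`, `t`, `p`.
#' @export
height_at_16 <- function(bundle, refs, window = 0.5) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  vis <- bundle$all_visits
  m <- match(vis$subject_id, bundle$subjects$subject_id)
  vis$sex <- bundle$subjects$sex[m]
  vis$end_age <- bundle$subjects$end_age[m]
  vis <- vis[abs(vis$age_years - 16) <= window & vis$age_years <= vis$end_age, ,
             drop = FALSE]
  out <- list()
  for (s in c("male", "female")) {
    vs <- vis[vis$sex == s, , drop = FALSE]
    if (!nrow(vs)) next
    vs <- vs[order(abs(vs$age_years - 16)), ]
    vs <- vs[!duplicated(vs$subject_id), , drop = FALSE]
    ref <- reference_mean_sd(16, s, "height", refs)
    tt <- if (nrow(vs) >= 2L)
      tryCatch(stats::t.test(vs$height_cm, mu = ref$mean),
               error = function(e) NULL) else NULL
    if (is.null(tt) && nrow(vs) >= 2L && stats::sd(vs$height_cm) == 0) {
      # constant sample: the statistic is defined by its limit
      diff <- vs$height_cm[1] - ref$mean
      tt <- list(statistic = if (diff == 0) 0 else sign(diff) * Inf,
                 p.value = if (diff == 0) 1 else 0)
    }
    out[[s]] <- data.frame(
      sex = s, n = nrow(vs), mean = mean(vs$height_cm),
      sd = stats::sd(vs$height_cm), ref_mean = ref$mean, ref_sd = ref$sd,
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
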