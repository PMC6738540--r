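#' Control parameters for the SITAR fitting loop
#'
#' @param tol relative change in the working log-likelihood below which the
#'   alternation is declared converged.
#' @param max_iter maximum number of linearize/solve iterations.
#' @param ascent_tol tolerated decrease of the working objective between
#'   iterations before the previous iterate is kept and iteration stops.
#' @param omega_cond_max condition-number threshold above which the
#'   random-effect covariance is treated as near-singular and the model is
#'   refitted with a diagonal covariance (with a warning).
#' @param verbose print the objective per iteration.
#' @return list of class `sitar_control`.
#' @export
sitar_control <- function(tol = 1e-6, max_iter = 200L, ascent_tol = 1e-8,
                          omega_cond_max = 1e8, verbose = FALSE) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 ascent_tol = ascent_tol, omega_cond_max = omega_cond_max,
                 verbose = isTRUE(verbose)), class = "sitar_control")
}

# parse `height ~ age | id`
.parse_sitar_formula <- function(formula) {
  if (length(formula) != 3L) stop("formula must look like height ~ age | id")
  rhs <- formula[[3L]]
  if (!(is.call(rhs) && identical(rhs[[1L]], as.name("|"))))
    stop("formula must look like height ~ age | id")
  list(y = deparse(formula[[2L]]), t = deparse(rhs[[2L]]),
       id = deparse(rhs[[3L]]))
}

# covariate design for one SITAR parameter
.param_design <- function(formula, covariates, keep_intercept = TRUE) {
  tr <- stats::terms(formula, data = covariates)
  mf <- stats::model.frame(tr, covariates, na.action = stats::na.fail)
  X <- stats::model.matrix(tr, mf)
  xlev <- stats::.getXlevels(tr, mf)
  if (!keep_intercept && "(Intercept)" %in% colnames(X))
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  list(X = X, terms = tr, xlevels = xlev)
}

#' Fit a shape-invariant (SITAR) growth model
#'
#' Models longitudinal height as a common natural-spline distance curve that
#' each subject shifts vertically (size, `a`, cm), shifts in age (timing,
#' `b`, years; positive = later growth spurt) and stretches in age
#' (intensity, `c`, log-rate; positive = steeper, shorter spurt):
#' `y_it = a_i + h((t - b_i) * exp(c_i))`. Each subject parameter is the sum
#' of covariate fixed effects on its mean and a subject-level random effect;
#' the three random effects have an unstructured 3x3 covariance and the
#' residual is Gaussian.
#'
#' Estimation iterates first-order linearization of the model in all three
#' subject parameters about the current fixed-effect estimates and
#' empirical-Bayes modes, solving the resulting linear mixed model by maximum
#' likelihood at each pass, until the working log-likelihood stabilises. The
#' reported log-likelihood, fixed-effect covariance and random-effect
#' estimates come from the final linearized step, the standard first-order
#' approximation for this model class.
#'
#' @param formula `height ~ age | subject_id`, naming columns of `data`.
#' @param data long data frame of visits (one row per measurement).
#' @param covariates per-subject data frame (one row per subject) carrying
#'   the id column and any covariates used in the parameter designs; may be
#'   `NULL` when all designs are `~ 1`.
#' @param df spline degrees of freedom (default 6; `df - 1` interior knots at
#'   equally spaced quantiles of the observed ages, boundary knots at their
#'   range).
#' @param a_formula,b_formula,c_formula covariate designs for the means of
#'   a, b and c. All three estimate an intercept (the a-intercept is the
#'   curve level; the b/c intercepts locate the curve in age and rate so the
#'   subject modes stay centred); covariate effects are offsets from the
#'   reference profile and contrasts between profiles never involve the
#'   intercepts.
#' @param log_age,log_height model on log-transformed age/height.
#' @param knots,boundary optional explicit spline knots (transformed scale).
#' @param control a [sitar_control()].
#' @return object of class `sitar`; see [predict.sitar()],
#'   [subject_effects()], [sitar_contrast()], [aphv()].
#' @examples
#' coh <- simulate_cohort(synthetic_config(n_subjects = 60), seed = 1)
#' vis <- coh$visits[coh$visits$age_years >= 8 & coh$visits$age_years <= 18, ]
#' fit <- sitar(height_cm ~ age_years | subject_id, vis,
#'              covariates = coh$subjects, b_formula = ~ haz_group)
#' summary(fit)
#' @export
sitar <- function(formula, data, covariates = NULL, df = 6,
                  a_formula = ~1, b_formula = ~1, c_formula = ~1,
                  log_age = FALSE, log_height = FALSE,
                  knots = NULL, boundary = NULL,
                  control = sitar_control()) {
  vars <- .parse_sitar_formula(formula)
  for (v in unlist(vars[c("y", "t")]))
    if (is.null(data[[v]])) stop("column ", v, " not found in data")
  if (is.null(data[[vars$id]])) stop("column ", vars$id, " not found in data")
  keep <- stats::complete.cases(data[, c(vars$y, vars$t, vars$id)])
  data <- data[keep, , drop = FALSE]

  id_obs <- as.character(data[[vars$id]])
  subj_ids <- sort(unique(id_obs))
  n_subj <- length(subj_ids)
  if (n_subj < 2L)
    stop("rank error: at least two subjects are required to fit a SITAR model")
  yy <- as.numeric(data[[vars$y]])
  tt <- as.numeric(data[[vars$t]])
  # canonical observation order (subject, age, value): the fit is then
  # exactly invariant to the row order of the input
  ord <- order(match(id_obs, subj_ids), tt, yy)
  id_obs <- id_obs[ord]; yy <- yy[ord]; tt <- tt[ord]
  inv_ord <- order(ord)
  id_f <- factor(id_obs, levels = subj_ids)
  if (log_height) yy <- log(yy)
  if (log_age) tt <- log(tt)
  n_obs <- length(yy)
  if (length(unique(tt)) < df + 1L)
    stop("rank error: need more distinct ages than spline degrees of freedom")

  if (is.null(covariates)) {
    covariates <- data.frame(id = subj_ids); names(covariates) <- vars$id
  }
  if (is.null(covariates[[vars$id]]))
    stop("covariates must carry the id column ", vars$id)
  covariates <- covariates[match(subj_ids, as.character(covariates[[vars$id]])), ,
                           drop = FALSE]
  if (anyNA(covariates[[vars$id]]))
    stop("covariates missing for some subjects in data")

  da <- .param_design(a_formula, covariates, keep_intercept = TRUE)
  db <- .param_design(b_formula, covariates, keep_intercept = TRUE)
  dc <- .param_design(c_formula, covariates, keep_intercept = TRUE)
  for (dz in list(a = da, b = db, c = dc)) {
    if (ncol(dz$X) && qr(dz$X)$rank < ncol(dz$X))
      stop("rank error: singular covariate design (aliased or empty levels) ",
           "in columns ", paste(colnames(dz$X), collapse = ", "))
  }
  ix <- match(id_obs, subj_ids)
  Xa <- da$X[ix, , drop = FALSE]
  Xb <- db$X[ix, , drop = FALSE]
  Xc <- dc$X[ix, , drop = FALSE]
  pa <- ncol(Xa); pb <- ncol(Xb); pc <- ncol(Xc)

  if (is.null(boundary)) {
    # place the boundary knots 10% beyond the observed age range so that
    # individual timing/intensity shifts keep the transformed ages inside
    # the cubic interior rather than on the linear tails
    rng <- range(tt)
    boundary <- rng + c(-0.1, 0.1) * diff(rng)
  }
  gen <- ncs_basis(tt, df = df, boundary = boundary, knots = knots)
  N0 <- gen$basis

  # initialization: pooled spline fit; a_i = subject mean residual
  init <- stats::lm.fit(cbind(`(Intercept)` = 1, N0), yy)
  s_coef <- init$coefficients[-1L]
  s_coef[is.na(s_coef)] <- 0
  beta <- c(s_coef,
            stats::setNames(c(init$coefficients[1L], rep(0, pa - 1L)),
                            colnames(Xa)),
            stats::setNames(rep(0, pb), colnames(Xb)),
            stats::setNames(rep(0, pc), colnames(Xc)))
  i_s <- seq_len(df)
  i_a <- df + seq_len(pa)
  i_b <- if (pb) df + pa + seq_len(pb) else integer(0)
  i_c <- if (pc) df + pa + pb + seq_len(pc) else integer(0)

  res0 <- yy - cbind(1, N0) %*% init$coefficients
  re <- cbind(a = as.numeric(tapply(res0, id_f, mean)), b = 0, c = 0)

  # warm start for the timing dimension: the pooled curve blurs the spurt,
  # and starting every subject at b = 0 can strand the alternation in a
  # local optimum.  Grid-align each subject's series to the pooled curve
  # (best time shift after refitting the subject intercept), then refit the
  # spline and intercepts at those shifts; two passes are enough to land in
  # the right basin.
  grid_b <- seq(-2.5, 2.5, by = 0.25)
  for (pass in 1:2) {
    rss <- vapply(grid_b, function(b0) {
      r <- yy - drop(ncs_eval(gen, tt - b0) %*% beta[i_s])
      as.numeric(rowsum((r - stats::ave(r, id_f))^2, id_f, reorder = FALSE))
    }, numeric(n_subj))
    re[, 2L] <- grid_b[max.col(-rss, ties.method = "first")]
    Nsh <- ncs_eval(gen, tt - re[ix, 2L])
    Ysh <- yy - stats::ave(yy, id_f)
    Nc <- Nsh - apply(Nsh, 2L, stats::ave, id_f)
    sc <- stats::lm.fit(Nc, Ysh)$coefficients
    sc[is.na(sc)] <- 0
    beta[i_s] <- sc
    ra <- yy - drop(Nsh %*% sc)
    beta[i_a][1L] <- mean(ra)
    re[, 1L] <- as.numeric(tapply(ra, id_f, mean)) - mean(ra)
  }

  # move the covariate-explained projection of the subject modes into the
  # fixed effects.  The subject-level parameters a_i + x'beta are unchanged,
  # so the likelihood is invariant; without this step the fixed/random split
  # can drift along a flat ridge and leave group contrasts in the modes.
  Xa_s <- da$X; Xb_s <- db$X; Xc_s <- dc$X
  center_split <- function(beta, re) {
    g <- qr.coef(qr(Xa_s), re[, 1L])
    g[is.na(g)] <- 0
    beta[i_a] <- beta[i_a] + g
    re[, 1L] <- re[, 1L] - drop(Xa_s %*% g)
    if (pb) {
      g <- qr.coef(qr(Xb_s), re[, 2L])
      g[is.na(g)] <- 0
      beta[i_b] <- beta[i_b] + g
      re[, 2L] <- re[, 2L] - drop(Xb_s %*% g)
    }
    if (pc) {
      g <- qr.coef(qr(Xc_s), re[, 3L])
      g[is.na(g)] <- 0
      beta[i_c] <- beta[i_c] + g
      re[, 3L] <- re[, 3L] - drop(Xc_s %*% g)
    }
    list(beta = beta, re = re)
  }

  # one linearize-and-solve pass: first-order expansion of the model in the
  # subject parameters about (beta, re), then ML fit of the working linear
  # mixed model
  linfit <- function(beta, re, diagonal, theta_start) {
    bfix <- if (pb) drop(Xb %*% beta[i_b]) else numeric(n_obs)
    cfix <- if (pc) drop(Xc %*% beta[i_c]) else numeric(n_obs)
    Bi <- bfix + re[ix, 2L]
    Ci <- cfix + re[ix, 3L]
    eC <- exp(Ci)
    u <- (tt - Bi) * eC
    N <- ncs_eval(gen, u)
    hp <- drop(ncs_eval(gen, u, 1L) %*% beta[i_s])
    zb <- -eC * hp
    zc <- u * hp
    X <- cbind(N, Xa,
               if (pb) Xb * zb,
               if (pc) Xc * zc)
    f <- drop(Xa %*% beta[i_a]) + re[ix, 1L] + drop(N %*% beta[i_s])
    ystar <- yy - f + drop(X %*% beta) +
      re[ix, 1L] + zb * re[ix, 2L] + zc * re[ix, 3L]

    dd <- data.frame(.y = ystar, .id = id_f, .za = 1, .zb = zb, .zc = zc)
    dd$.X <- X
    form <- if (diagonal)
      .y ~ 0 + .X + (0 + .za | .id) + (0 + .zb | .id) + (0 + .zc | .id)
    else
      .y ~ 0 + .X + (0 + .za + .zb + .zc | .id)
    lf <- suppressWarnings(suppressMessages(lme4::lmer(
      form, data = dd, REML = FALSE,
      start = theta_start,
      control = lme4::lmerControl(
        calc.derivs = FALSE,
        check.conv.grad = "ignore", check.conv.singular = "ignore",
        check.conv.hess = "ignore",
        check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore"))))
    beta_hat <- stats::setNames(as.numeric(lme4::fixef(lf)), names(beta))
    rr <- lme4::ranef(lf)$.id
    re_hat <- matrix(0, n_subj, 3L,
                     dimnames = list(subj_ids, c("a", "b", "c")))
    got <- intersect(c(".za", ".zb", ".zc"), colnames(rr))
    re_hat[match(rownames(rr), subj_ids),
           match(got, c(".za", ".zb", ".zc"))] <- as.matrix(rr[, got])
    re_hat <- refine_modes(beta_hat, re_hat, .extract_omega(lf),
                           stats::sigma(lf))
    cs <- center_split(beta_hat, re_hat)
    beta_hat <- cs$beta; re_hat <- cs$re
    list(lf = lf, ll = as.numeric(stats::logLik(lf)),
         beta_hat = beta_hat, re_hat = re_hat,
         omega = .extract_omega(lf), sigma = stats::sigma(lf),
         theta = list(theta = lme4::getME(lf, "theta")))
  }

  # discrete escape move: grid-realign each subject's timing mode against
  # the current curve and fixed effects (penalized by the current prior),
  # used when the continuous updates stall.  Only accepted if the working
  # objective improves.
  realign_b <- function(beta, re, omega, sigma) {
    sig2 <- max(sigma, 1e-8)^2
    om_b <- max(omega[2L, 2L], 1e-6)
    bfix <- if (pb) drop(Xb %*% beta[i_b]) else numeric(n_obs)
    cfix <- if (pc) drop(Xc %*% beta[i_c]) else numeric(n_obs)
    afix <- drop(Xa %*% beta[i_a])
    best <- rep(Inf, n_subj)
    best_b <- re[, 2L]
    best_a <- re[, 1L]
    for (b0 in grid_b) {
      u <- (tt - bfix - b0) * exp(cfix + re[ix, 3L])
      r <- yy - afix - drop(ncs_eval(gen, u) %*% beta[i_s])
      rm <- stats::ave(r, id_f)  # subject intercept refit per shift
      tot <- as.numeric(rowsum((r - rm)^2, id_f, reorder = FALSE)) / sig2 +
        b0^2 / om_b
      upd <- tot < best
      best[upd] <- tot[upd]
      best_b[upd] <- b0
      best_a[upd] <- as.numeric(tapply(r, id_f, mean))[upd]
    }
    re[, 2L] <- best_b
    re[, 1L] <- best_a
    refine_modes(beta, re, omega, sigma)
  }

  # penalized nonlinear least squares for the subject modes: given fixed
  # effects and variance components, Gauss-Newton on
  # ||y_i - f_i(r)||^2 / sigma^2 + r' omega^{-1} r per subject, with global
  # step halving.  This is the PNLS half of the alternation; without it the
  # one-step BLUP modes lag the posterior optimum and attenuate the fixed
  # effects.
  refine_modes <- function(beta, re, omega, sigma, n_gn = 20L) {
    sig2 <- max(sigma, 1e-8)^2
    Oi <- solve(omega + diag(1e-10, 3L))
    bfix <- if (pb) drop(Xb %*% beta[i_b]) else numeric(n_obs)
    cfix <- if (pc) drop(Xc %*% beta[i_c]) else numeric(n_obs)
    afix <- drop(Xa %*% beta[i_a])
    resid_parts <- function(re) {
      u <- (tt - bfix - re[ix, 2L]) * exp(cfix + re[ix, 3L])
      N <- ncs_eval(gen, u)
      hp <- drop(ncs_eval(gen, u, 1L) %*% beta[i_s])
      e <- yy - afix - re[ix, 1L] - drop(N %*% beta[i_s])
      list(u = u, hp = hp, e = e)
    }
    pen_obj <- function(re, e)
      sum(e^2) / sig2 + sum((re %*% Oi) * re)
    rp <- resid_parts(re)
    obj <- pen_obj(re, rp$e)
    for (it in seq_len(n_gn)) {
      eC <- exp(cfix + re[ix, 3L])
      zb <- -eC * rp$hp
      zc <- rp$u * rp$hp
      Z <- cbind(1, zb, zc)
      cross <- rowsum(cbind(Z[, 1L] * Z, Z[, 2L] * Z[, 2L:3L], zc * zc,
                            Z * rp$e), id_f, reorder = FALSE) / sig2
      delta <- re
      for (i in seq_len(n_subj)) {
        A <- matrix(cross[i, c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3L, 3L) + Oi
        g <- cross[i, 7:9] - drop(Oi %*% re[i, ])
        delta[i, ] <- tryCatch(solve(A, g), error = function(e) c(0, 0, 0))
      }
      step <- 1
      repeat {
        re_new <- re + step * delta
        rp_new <- resid_parts(re_new)
        obj_new <- pen_obj(re_new, rp_new$e)
        if (obj_new <= obj + 1e-10 || step < 1 / 64) break
        step <- step / 2
      }
      if (obj_new > obj) break
      moved <- max(abs(step * delta))
      re <- re_new; rp <- rp_new
      improved <- obj - obj_new
      obj <- obj_new
      if (moved < 1e-8 || improved < 1e-8 * (abs(obj) + 1)) break
    }
    re
  }

  # damped alternation: propose the full update of the linearization point;
  # if the working objective drops, halve the step back toward the current
  # point.  Accepted objectives are non-decreasing by construction.
  run_loop <- function(beta, re, diagonal = FALSE) {
    cur <- linfit(beta, re, diagonal, NULL)
    if (control$verbose)
      message(sprintf("iter %3d: working logLik %.6f", 1L, cur$ll))
    trace <- cur$ll
    converged <- FALSE
    iter <- 1L
    step <- 1
    while (iter < control$max_iter) {
      prop_beta <- beta + step * (cur$beta_hat - beta)
      prop_re <- re + step * (cur$re_hat - re)
      cand <- linfit(prop_beta, prop_re, diagonal, cur$theta)
      iter <- iter + 1L
      if (control$verbose)
        message(sprintf("iter %3d: working logLik %.6f (step %.3g)%s",
                        iter, cand$ll, step,
                        if (cand$ll < cur$ll - control$ascent_tol)
                          " rejected" else ""))
      if (cand$ll >= cur$ll - control$ascent_tol) {
        rel <- abs(cand$ll - cur$ll) / (abs(cur$ll) + 1)
        beta <- prop_beta; re <- prop_re; cur <- cand
        trace <- c(trace, cand$ll)
        step <- min(1, 2 * step)
        if (rel <= control$tol) { converged <- TRUE; break }
      } else {
        step <- step / 2
        if (step < 1 / 64) {
          # continuous updates stalled; try one discrete timing realignment
          re_jump <- realign_b(beta, re, cur$omega, cur$sigma)
          cand <- linfit(beta, re_jump, diagonal, cur$theta)
          iter <- iter + 1L
          if (control$verbose)
            message(sprintf("iter %3d: working logLik %.6f (realign)%s",
                            iter, cand$ll,
                            if (cand$ll <= cur$ll + control$ascent_tol)
                              " rejected" else ""))
          if (cand$ll > cur$ll + control$ascent_tol) {
            re <- re_jump; cur <- cand
            trace <- c(trace, cand$ll)
            step <- 1
            next
          }
          converged <- TRUE  # stationary within linearization noise
          break
        }
      }
    }
    list(beta = cur$beta_hat, re = cur$re_hat, lf = cur$lf, ll = cur$ll,
         trace = trace, iterations = iter, converged = converged)
  }

  st <- run_loop(beta, re, diagonal = FALSE)
  omega <- .extract_omega(st$lf)
  if (.cond_number(omega) > control$omega_cond_max) {
    warning("near-singular random-effect covariance; refitting with a ",
            "diagonal covariance")
    st <- run_loop(st$beta, st$re, diagonal = TRUE)
    omega <- .extract_omega(st$lf)
  }
  beta <- st$beta
  re <- st$re

  sig <- stats::sigma(st$lf)
  V <- as.matrix(stats::vcov(st$lf))
  dimnames(V) <- list(names(beta), names(beta))
  n_omega <- if (isTRUE(attr(omega, "diagonal"))) 3L else 6L
  k <- length(beta) + n_omega + 1L

  # final fitted values at the accepted iterate
  bfix <- if (pb) drop(Xb %*% beta[i_b]) else numeric(n_obs)
  cfix <- if (pc) drop(Xc %*% beta[i_c]) else numeric(n_obs)
  u <- (tt - bfix - re[ix, 2L]) * exp(cfix + re[ix, 3L])
  fitted_t <- drop(Xa %*% beta[i_a]) + re[ix, 1L] +
    drop(ncs_eval(gen, u) %*% beta[i_s])

  curve <- sitar_curve(gen, beta[i_s], intercept = unname(beta[i_a][1L]))
  out <- structure(list(
    curve = curve,
    beta = beta,
    beta_a = beta[i_a], beta_b = beta[i_b], beta_c = beta[i_c],
    index = list(s = i_s, a = i_a, b = i_b, c = i_c),
    vcov = V,
    omega = omega, sigma = sig,
    loglik = st$ll, k_params = k,
    n_obs = n_obs, n_subjects = n_subj,
    converged = isTRUE(st$converged), iterations = st$iterations,
    trace = st$trace,
    ranef = data.frame(subject_id = subj_ids, a_i = re[, 1L],
                       b_i = re[, 2L], c_i = re[, 3L],
                       stringsAsFactors = FALSE, row.names = NULL),
    designs = list(a = da[c("terms", "xlevels")], b = db[c("terms", "xlevels")],
                   c = dc[c("terms", "xlevels")]),
    formulas = list(a = a_formula, b = b_formula, c = c_formula),
    log_age = log_age, log_height = log_height,
    vars = vars,
    fitted = (if (log_height) exp(fitted_t) else fitted_t)[inv_ord],
    y = (if (log_height) exp(yy) else yy)[inv_ord],
    call = match.call()), class = "sitar")
  out
}

.extract_omega <- function(lf) {
  vc <- lme4::VarCorr(lf)
  if (length(vc) == 1L) {
    om <- as.matrix(vc[[1L]])
    attr(om, "stddev") <- NULL; attr(om, "correlation") <- NULL
    dimnames(om) <- list(c("a", "b", "c"), c("a", "b", "c"))
    attr(om, "diagonal") <- FALSE
  } else {
    v <- vapply(vc, function(m) m[1L, 1L], numeric(1))
    nm <- vapply(vc, function(m) colnames(m), character(1))
    om <- diag(v[order(match(nm, c(".za", ".zb", ".zc")))])
    dimnames(om) <- list(c("a", "b", "c"), c("a", "b", "c"))
    attr(om, "diagonal") <- TRUE
  }
  om
}

.cond_number <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}
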