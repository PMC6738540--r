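#' Serialize a fitted SITAR model to a plain-text file
#'
#' Writes a key-value text representation (full 17-digit precision, so
#' numbers survive a round trip bit-exactly) of the spline knots and
#' coefficients, named fixed effects, fixed-effect covariance, random-effect
#' covariance, residual SD, log-likelihood and convergence metadata.
#' [read_sitar()] reconstructs a `sitar` object able to predict, form
#' contrasts and compute APHV; subject-level effects are exported separately
#' (see [subject_effects()]).
#'
#' @param fit a fitted `sitar` model.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_sitar <- function(fit, path) {
  stopifnot(inherits(fit, "sitar"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  str1 <- function(x) paste(x, collapse = "\t")
  ln <- c(
    "format: growthspurt sitar fit v1",
    paste0("df: ", fit$curve$basis$df),
    paste0("boundary: ", num(fit$curve$basis$boundary)),
    paste0("knots: ", num(fit$curve$basis$knots)),
    paste0("coef: ", num(fit$curve$coef)),
    paste0("intercept: ", num(fit$curve$intercept)),
    paste0("beta_names: ", str1(names(fit$beta))),
    paste0("beta: ", num(fit$beta)),
    paste0("index_s: ", num(fit$index$s)),
    paste0("index_a: ", num(fit$index$a)),
    paste0("index_b: ", num(fit$index$b)),
    paste0("index_c: ", num(fit$index$c)),
    paste0("vcov: ", num(as.numeric(fit$vcov))),
    paste0("omega: ", num(as.numeric(fit$omega))),
    paste0("omega_diagonal: ", isTRUE(attr(fit$omega, "diagonal"))),
    paste0("sigma: ", num(fit$sigma)),
    paste0("loglik: ", num(fit$loglik)),
    paste0("k_params: ", fit$k_params),
    paste0("n_obs: ", fit$n_obs),
    paste0("n_subjects: ", fit$n_subjects),
    paste0("converged: ", fit$converged),
    paste0("iterations: ", fit$iterations),
    paste0("log_age: ", fit$log_age),
    paste0("log_height: ", fit$log_height),
    paste0("formula_a: ", deparse(fit$formulas$a)),
    paste0("formula_b: ", deparse(fit$formulas$b)),
    paste0("formula_c: ", deparse(fit$formulas$c)))
  for (p in c("a", "b", "c")) {
    xl <- fit$designs[[p]]$xlevels
    for (v in names(xl))
      ln <- c(ln, paste0("xlevels_", p, ": ", v, "=", str1(xl[[v]])))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a serialized SITAR model
#'
#' @param path file written by [write_sitar()].
#' @return object of class `sitar` (without per-observation data).
#' @export
read_sitar <- function(path) {
  ln <- readLines(path)
  if (!identical(ln[1], "format: growthspurt sitar fit v1"))
    stop("not a growthspurt sitar fit file")
  kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
  get1 <- function(k) vals[match(k, keys)]
  nums <- function(k) as.numeric(strsplit(get1(k), " ", fixed = TRUE)[[1L]])
  ints <- function(k) {
    v <- get1(k)
    if (is.na(v) || v == "") integer(0) else as.integer(nums(k))
  }
  lgl <- function(k) identical(get1(k), "TRUE")

  df <- as.integer(get1("df"))
  gen <- ncs_basis(numeric(0), df = df, boundary = nums("boundary"),
                   knots = nums("knots"))
  beta <- stats::setNames(nums("beta"),
                          strsplit(get1("beta_names"), "\t", fixed = TRUE)[[1L]])
  p <- length(beta)
  V <- matrix(nums("vcov"), p, p, dimnames = list(names(beta), names(beta)))
  omega <- matrix(nums("omega"), 3L, 3L,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  attr(omega, "diagonal") <- lgl("omega_diagonal")
  idx <- list(s = ints("index_s"), a = ints("index_a"),
              b = ints("index_b"), c = ints("index_c"))
  forms <- lapply(c(a = "formula_a", b = "formula_b", c = "formula_c"),
                  function(k) stats::as.formula(get1(k)))
  xlev <- list(a = list(), b = list(), c = list())
  for (pset in c("a", "b", "c")) {
    sel <- which(keys == paste0("xlevels_", pset))
    for (i in sel) {
      parts <- regmatches(vals[i], regexpr("=", vals[i]), invert = TRUE)[[1L]]
      xlev[[pset]][[parts[1L]]] <-
        strsplit(parts[2L], "\t", fixed = TRUE)[[1L]]
    }
  }
  designs <- lapply(c(a = "a", b = "b", c = "c"), function(pset) {
    fake <- as.data.frame(lapply(xlev[[pset]], function(l) factor(l[1], l)))
    list(terms = stats::terms(forms[[pset]],
                              data = if (ncol(fake)) fake else NULL),
         xlevels = xlev[[pset]])
  })
  structure(list(
    curve = sitar_curve(gen, nums("coef"), nums("intercept")),
    beta = beta,
    beta_a = beta[idx$a], beta_b = beta[idx$b], beta_c = beta[idx$c],
    index = idx, vcov = V, omega = omega,
    sigma = nums("sigma"), loglik = nums("loglik"),
    k_params = as.integer(get1("k_params")),
    n_obs = as.integer(get1("n_obs")),
    n_subjects = as.integer(get1("n_subjects")),
    converged = lgl("converged"),
    iterations = as.integer(get1("iterations")),
    ranef = NULL,
    designs = designs, formulas = forms,
    log_age = lgl("log_age"), log_height = lgl("log_height"),
    call = NULL), class = "sitar")
}
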