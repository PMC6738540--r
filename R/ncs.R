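#' Natural cubic spline basis with analytic derivatives
#'
#' Builds a natural cubic spline basis generator of a given number of degrees
#' of freedom, with interior knots placed at equally spaced quantiles of the
#' supplied ages and boundary knots at their range. The basis spans the usual
#' B-spline space subject to the natural constraint (zero second derivative at
#' and beyond the boundary knots); beyond the boundary the basis continues
#' linearly. Unlike [splines::ns()], the generator evaluates analytic first
#' and second derivatives, which the shape-invariant growth model needs for
#' velocity curves and for its linearization steps.
#'
#' @param ages numeric vector of ages (years) used to place knots.
#' @param df integer degrees of freedom (number of basis columns), at least 3.
#'   `df` columns imply `df - 1` interior knots.
#' @param boundary optional length-2 numeric giving the boundary knots;
#'   defaults to `range(ages)`.
#' @param knots optional explicit interior knots (overrides quantile
#'   placement).
#' @return An object of class `ncs_basis` with elements `df`, `knots`,
#'   `boundary`, `proj` (the natural-constraint projection applied to the
#'   cubic B-spline design), and `basis`/`deriv`, the basis and
#'   first-derivative basis evaluated at `ages`.
#' @examples
#' b <- ncs_basis(seq(8, 18, by = 0.1), df = 6)
#' dim(b$basis)      # 101 x 6
#' length(b$knots)   # 5 interior knots
#' @seealso [ncs_eval()]
#' @export
ncs_basis <- function(ages, df, boundary = NULL, knots = NULL) {
  if (df < 3L) stop("df must be at least 3")
  ages <- as.numeric(ages)
  if (is.null(boundary)) boundary <- range(ages)
  boundary <- sort(as.numeric(boundary))
  if (is.null(knots)) {
    n_interior <- df - 1L
    inside <- ages >= boundary[1] & ages <= boundary[2]
    if (length(unique(ages[inside])) < df + 1L)
      stop("rank error: need at least df + 1 distinct ages to place knots")
    probs <- seq(0, 1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
    knots <- unname(stats::quantile(ages[inside], probs))
  }
  knots <- sort(as.numeric(knots))
  if (length(unique(c(boundary, knots))) < length(knots) + 2L ||
      any(knots <= boundary[1]) || any(knots >= boundary[2]))
    stop("too few distinct ages to place ", df - 1L,
         " interior knots strictly inside the boundary")
  aug <- sort(c(rep(boundary, 4L), knots))
  # natural constraint: zero 2nd derivative at both boundary knots.  The
  # first B-spline column is dropped (intercept handled by the model), then
  # the design is projected onto the null space of the constraint rows.
  const <- splines::splineDesign(aug, boundary, ord = 4L, derivs = c(2L, 2L))
  const <- const[, -1L, drop = FALSE]
  qc <- qr(t(const))
  proj <- qr.Q(qc, complete = TRUE)[, -(1:2), drop = FALSE]
  out <- structure(
    list(df = as.integer(df), knots = knots, boundary = boundary,
         aug_knots = aug, proj = proj),
    class = "ncs_basis")
  out$basis <- ncs_eval(out, ages)
  out$deriv <- ncs_eval(out, ages, deriv = 1L)
  out
}

#' Evaluate a natural cubic spline basis
#'
#' Evaluates the basis (or its first or second derivative) at arbitrary ages.
#' Outside the boundary knots the spline is extended linearly, so the second
#' derivative is identically zero there.
#'
#' @param object an `ncs_basis` generator from [ncs_basis()].
#' @param x ages at which to evaluate.
#' @param deriv 0 (values), 1 (first derivative) or 2 (second derivative).
#' @return numeric matrix, `length(x)` rows by `df` columns.
#' @export
ncs_eval <- function(object, x, deriv = 0L) {
  stopifnot(inherits(object, "ncs_basis"), deriv %in% 0:2)
  x <- as.numeric(x)
  b <- object$boundary
  out <- matrix(0, length(x), object$df)
  inside <- x >= b[1] & x <= b[2]
  bs_at <- function(pts, d) {
    m <- splines::splineDesign(object$aug_knots, pts, ord = 4L,
                               derivs = rep(d, length(pts)))
    m[, -1L, drop = FALSE] %*% object$proj
  }
  if (any(inside)) out[inside, ] <- bs_at(x[inside], deriv)
  if (any(!inside)) {
    # linear tails: N(x) = N(b) + N'(b) (x - b), N'(x) = N'(b), N''(x) = 0
    for (side in 1:2) {
      sel <- if (side == 1L) !inside & x < b[1] else !inside & x > b[2]
      if (!any(sel)) next
      if (deriv == 0L) {
        v0 <- bs_at(b[side], 0L)
        v1 <- bs_at(b[side], 1L)
        out[sel, ] <- rep(1, sum(sel)) %o% drop(v0) +
          (x[sel] - b[side]) %o% drop(v1)
      } else if (deriv == 1L) {
        out[sel, ] <- rep(1, sum(sel)) %o% drop(bs_at(b[side], 1L))
      } # deriv 2: stays zero
    }
  }
  dimnames(out) <- list(NULL, paste0("s", seq_len(object$df)))
  out
}

#' Population growth curve of a shape-invariant model
#'
#' A `sitar_curve` couples a natural-spline basis with fitted coefficients and
#' an intercept; it is the distance curve h(t) that individual size, timing
#' and intensity effects transform.
#'
#' @param basis an `ncs_basis` generator.
#' @param coef spline coefficients (length `df`), in cm per basis column.
#' @param intercept curve intercept in cm.
#' @return object of class `sitar_curve`.
#' @export
sitar_curve <- function(basis, coef, intercept = 0) {
  stopifnot(inherits(basis, "ncs_basis"), length(coef) == basis$df)
  structure(list(basis = basis, coef = as.numeric(coef),
                 intercept = as.numeric(intercept)),
            class = "sitar_curve")
}

curve_eval <- function(curve, x, deriv = 0L) {
  y <- drop(ncs_eval(curve$basis, x, deriv) %*% curve$coef)
  if (deriv == 0L) y + curve$intercept else y
}

#' @export
print.ncs_basis <- function(x, ...) {
  cat("Natural cubic spline basis: df =", x$df, "\n")
  cat("  boundary knots:", format(x$boundary, digits = 4), "\n")
  cat("  interior knots:", format(x$knots, digits = 4), "\n")
  invisible(x)
}
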