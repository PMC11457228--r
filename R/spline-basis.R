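#' Natural cubic spline basis with analytic derivatives
#'
#' Constructs a natural cubic spline basis (linear beyond the boundary knots,
#' continuous second derivatives everywhere) that can be evaluated together
#' with its first and second derivatives at arbitrary ages. The construction
#' mirrors the usual B-spline-with-natural-constraints approach: a cubic
#' B-spline design is projected onto the null space of the boundary
#' second-derivative constraints, and the leading (constant-like) column is
#' dropped so the basis can be combined with an explicit intercept.
#'
#' @param ages numeric vector of ages (decimal years) whose range and
#'   quantiles define the knots.
#' @param df integer, number of basis functions; `df - 1` interior knots are
#'   placed at equally spaced quantiles of `ages`, boundary knots at the
#'   range limits.
#' @param interior_knots optional numeric vector of interior knots overriding
#'   quantile placement.
#' @param boundary_knots optional length-2 numeric vector overriding the age
#'   range limits.
#' @return an object of class `nspline_basis` with fields `interior_knots`,
#'   `boundary_knots`, `df` and the projection matrix used for evaluation.
#' @examples
#' b <- natural_spline_basis(seq(7, 16.5, 0.25), df = 6)
#' X <- nsb_eval(b, seq(8, 15, 0.5))
#' @export
natural_spline_basis <- function(ages, df = NULL, interior_knots = NULL,
                                 boundary_knots = NULL) {
  stopifnot(is.numeric(ages), length(ages) >= 2L)
  if (is.null(interior_knots) && (is.null(df) || is.na(df) || df < 2))
    stop("df must be at least 2 when interior knots are not supplied")
  if (is.null(boundary_knots)) boundary_knots <- range(ages)
  if (diff(boundary_knots) <= 0) stop("ages must span a positive range")
  if (is.null(interior_knots)) {
    if (df - 1L > length(unique(ages)) - 2L)
      stop("df exceeds what the distinct ages can support")
    probs <- seq_len(df - 1L) / df
    interior_knots <- unname(stats::quantile(ages, probs, type = 7))
  }
  interior_knots <- as.numeric(interior_knots)
  if (is.unsorted(interior_knots, strictly = TRUE))
    stop("interior knots must be strictly increasing")
  if (any(interior_knots <= boundary_knots[1]) ||
      any(interior_knots >= boundary_knots[2]))
    stop("interior knots must lie strictly inside the boundary knots")

  aug <- c(rep(boundary_knots[1], 4L), interior_knots, rep(boundary_knots[2], 4L))
  # null-space projection of the natural (zero curvature at boundaries) constraints
  const <- splines::splineDesign(aug, boundary_knots, ord = 4L,
                                 derivs = c(2L, 2L))
  qr_c <- qr(t(const))
  proj <- qr.Q(qr_c, complete = TRUE)[, -(1:2), drop = FALSE]

  structure(
    list(interior_knots = interior_knots,
         boundary_knots = as.numeric(boundary_knots),
         df = length(interior_knots) + 1L,
         aug_knots = aug,
         proj = proj),
    class = "nspline_basis")
}

#' Evaluate a natural spline basis (or a derivative of it)
#'
#' Values outside the boundary knots are extended linearly, consistent with
#' the natural (zero second derivative) condition: first derivatives are
#' constant and second derivatives zero beyond the boundaries.
#'
#' @param basis an `nspline_basis` object.
#' @param x ages at which to evaluate.
#' @param deriv 0, 1 or 2: the derivative order.
#' @return matrix with `length(x)` rows and `basis$df` columns.
#' @export
nsb_eval <- function(basis, x, deriv = 0L) {
  stopifnot(inherits(basis, "nspline_basis"), deriv %in% 0:2)
  x <- as.numeric(x)
  lo <- basis$boundary_knots[1]; hi <- basis$boundary_knots[2]
  inside <- x >= lo & x <= hi
  out <- matrix(0, length(x), basis$df)

  ev <- function(xx, d) {
    D <- splines::splineDesign(basis$aug_knots, xx, ord = 4L,
                               derivs = rep(d, length(xx)))
    (D %*% basis$proj)[, -1L, drop = FALSE]
  }
  if (any(inside)) out[inside, ] <- ev(x[inside], deriv)
  if (any(!inside)) {
    xo <- x[!inside]
    bk <- ifelse(xo < lo, lo, hi)
    if (deriv == 0L) {
      out[!inside, ] <- ev(bk, 0L) + (xo - bk) * ev(bk, 1L)
    } else if (deriv == 1L) {
      out[!inside, ] <- ev(bk, 1L)
    } # deriv == 2 stays 0
  }
  out
}

#' @export
print.nspline_basis <- function(x, ...) {
  cat("Natural cubic spline basis\n")
  cat("  df:", x$df, "\n")
  cat("  boundary knots:", format(x$boundary_knots, digits = 4), "\n")
  cat("  interior knots:", format(x$interior_knots, digits = 4), "\n")
  invisible(x)
}
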