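#' Spline basis specification
#'
#' Describes a one-dimensional spline basis, either a natural cubic spline
#' (linear beyond the boundary knots; used for seasonality control and for
#' the lag-response function) or a B-spline (used for the exposure-response
#' function, with interior knots typically placed at percentiles of the
#' observed exposure distribution).
#'
#' Degrees of freedom are derived from the knots rather than supplied:
#' a natural cubic spline with `k` interior knots contributes `k + 1` columns
#' without an intercept and `k + 2` with one; a degree-`d` B-spline with `k`
#' interior knots contributes `k + d` columns without an intercept and
#' `k + d + 1` with one.
#'
#' @param family `"natural_cubic"` or `"bspline"`.
#' @param interior_knots numeric vector of interior knot positions, strictly
#'   inside the boundary knots (may be empty).
#' @param boundary_knots length-2 numeric, `boundary_knots[1] < boundary_knots[2]`.
#' @param degree polynomial degree, B-splines only (default 3, cubic).
#' @param intercept logical; keep the full basis (`TRUE`) or drop a column so
#'   the basis is full-rank alongside a separate model intercept (`FALSE`).
#' @return An object of class `"basis_spec"`.
#' @seealso [eval_basis()], [percentile_knots()]
#' @export
basis_spec <- function(family = c("natural_cubic", "bspline"),
                       interior_knots = numeric(0),
                       boundary_knots,
                       degree = 3L,
                       intercept = FALSE) {
  family <- match.arg(family)
  boundary_knots <- as.numeric(boundary_knots)
  interior_knots <- sort(as.numeric(interior_knots))
  if (length(boundary_knots) != 2L || !all(is.finite(boundary_knots)))
    stop("'boundary_knots' must be two finite numbers")
  if (boundary_knots[1L] >= boundary_knots[2L])
    stop("boundary_knots[1] must be strictly less than boundary_knots[2]")
  if (length(interior_knots) &&
      (any(!is.finite(interior_knots)) ||
       any(interior_knots <= boundary_knots[1L]) ||
       any(interior_knots >= boundary_knots[2L])))
    stop("interior knots must be finite and strictly inside the boundary knots")
  if (family == "bspline") {
    degree <- as.integer(degree)
    if (degree < 1L) stop("'degree' must be >= 1 for B-splines")
  } else {
    degree <- 3L
  }
  df <- switch(family,
    natural_cubic = length(interior_knots) + 1L + as.integer(intercept),
    bspline = length(interior_knots) + degree + as.integer(intercept))
  structure(
    list(family = family, interior_knots = interior_knots,
         boundary_knots = boundary_knots, degree = degree,
         intercept = isTRUE(intercept), df = df),
    class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> %s%s, df = %d\n", x$family,
              if (x$family == "bspline") sprintf(" (degree %d)", x$degree) else "",
              x$df))
  cat(sprintf("  boundary knots: [%g, %g]\n", x$boundary_knots[1L], x$boundary_knots[2L]))
  if (length(x$interior_knots))
    cat("  interior knots:", paste(signif(x$interior_knots, 6), collapse = ", "), "\n")
  cat("  intercept:", x$intercept, "\n")
  invisible(x)
}

#' Empirical percentile knots
#'
#' Computes knot locations at the requested percentiles of an observed
#' series, using the linear-interpolation quantile definition
#' (`stats::quantile` type 7) throughout the package. Exposure-response
#' splines conventionally place interior knots at the 10th, 75th and 90th
#' percentiles of each location's own temperature distribution.
#'
#' @param values numeric vector of observations (`NA` dropped).
#' @param percentiles strictly increasing percentiles in (0, 100).
#' @return numeric vector of knot values, one per percentile.
#' @examples
#' percentile_knots(1:100, c(10, 75, 90))
#' @export
percentile_knots <- function(values, percentiles = c(10, 75, 90)) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("'values' is empty")
  if (any(!is.finite(values))) stop("'values' contains non-finite entries")
  percentiles <- as.numeric(percentiles)
  if (!length(percentiles) || any(!is.finite(percentiles)) ||
      any(percentiles <= 0) || any(percentiles >= 100))
    stop("'percentiles' must lie strictly within (0, 100)")
  if (is.unsorted(percentiles, strictly = TRUE))
    stop("'percentiles' must be strictly increasing")
  unname(stats::quantile(values, probs = percentiles / 100, type = 7))
}

#' Evaluate a spline basis
#'
#' Evaluates the basis described by a [basis_spec()] at arbitrary points.
#' Natural cubic splines (via [splines::ns()]) have zero second derivative
#' outside the boundary knots and so extrapolate linearly. B-splines (via
#' [splines::bs()]) are only defined on the knot span; points outside the
#' boundary knots raise an error unless `clamp = TRUE`, in which case they
#' are evaluated at the nearest boundary.
#'
#' The result is a pure function of `(x, spec)`: identical inputs give
#' bit-identical matrices.
#'
#' @param x numeric vector of evaluation points; `NA` rows propagate as `NA`.
#' @param spec a [basis_spec()].
#' @param clamp logical; clamp B-spline evaluation points to the boundary
#'   knots instead of raising an error (default `FALSE`).
#' @return numeric matrix, `length(x)` rows and `spec$df` columns, with the
#'   spec attached as attribute `"spec"`.
#' @export
eval_basis <- function(x, spec, clamp = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  x <- as.numeric(x)
  if (any(is.infinite(x) | is.nan(x)))
    stop("'x' contains non-finite values (NA is allowed and propagates)")
  ok <- !is.na(x)
  xe <- x[ok]
  if (spec$family == "bspline") {
    out_lo <- xe < spec$boundary_knots[1L]
    out_hi <- xe > spec$boundary_knots[2L]
    if (any(out_lo | out_hi)) {
      if (!clamp)
        stop("B-spline evaluation points outside the boundary knots; ",
             "set clamp = TRUE to evaluate at the nearest boundary")
      xe[out_lo] <- spec$boundary_knots[1L]
      xe[out_hi] <- spec$boundary_knots[2L]
    }
    b <- splines::bs(xe, knots = spec$interior_knots, degree = spec$degree,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  } else {
    b <- splines::ns(xe, knots = spec$interior_knots,
                     Boundary.knots = spec$boundary_knots,
                     intercept = spec$intercept)
  }
  b <- unclass(b)[, seq_len(spec$df), drop = FALSE]
  if (all(ok)) {
    m <- b
  } else {
    m <- matrix(NA_real_, length(x), spec$df)
    m[ok, ] <- b
  }
  dimnames(m) <- list(NULL, sprintf("b%d", seq_len(spec$df)))
  attr(m, "spec") <- spec
  m
}

# Interior-knot positions for the lag-response spline: nk knots equally
# spaced on the log(lag + 1) scale over lags 0..L, giving {1, 3} for L = 7
# with 2 knots and roughly {1.2, 3.7, 9.2} for L = 21 with 3 knots.
log_lag_knots <- function(max_lag, n_knots) {
  stopifnot(max_lag >= 1L, n_knots >= 0L)
  if (n_knots == 0L) return(numeric(0))
  exp(log(max_lag + 1) * seq_len(n_knots) / (n_knots + 1)) - 1
}
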