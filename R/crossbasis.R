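#' Cross-basis specification for a distributed-lag non-linear model
#'
#' Pairs an exposure-dimension basis with a lag-dimension basis evaluated on
#' the integer lags `0..max_lag`. The cross-basis is the tensor product of
#' the two: column `(j, k)` of the design block at day `t` is
#' `sum_l varbasis(x[t - l])[j] * lagbasis(l)[k]`.
#'
#' @param var_spec [basis_spec()] for the exposure dimension.
#' @param lag_spec [basis_spec()] for the lag dimension; its boundary knots
#'   must be `c(0, max_lag)`.
#' @param max_lag maximum lag in days (L >= 0).
#' @return An object of class `"crossbasis_spec"`.
#' @export
crossbasis_spec <- function(var_spec, lag_spec, max_lag) {
  stopifnot(inherits(var_spec, "basis_spec"), inherits(lag_spec, "basis_spec"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("'max_lag' must be >= 0")
  structure(list(var_spec = var_spec, lag_spec = lag_spec, max_lag = max_lag),
            class = "crossbasis_spec")
}

#' Default cross-basis specification for a temperature series
#'
#' Builds the cross-basis used throughout the pipeline: exposure dimension a
#' B-spline (default cubic) with interior knots at the 10th, 75th and 90th
#' percentiles of the series and boundary knots at its range; lag dimension a
#' natural cubic spline with intercept over lags `0..max_lag`, interior knots
#' equally spaced on the log(lag + 1) scale. The lag-knot count follows the
#' lag window: 2 knots for `max_lag = 7`, 3 knots for longer windows
#' (overridable via `lag_knots`).
#'
#' @param tmean numeric exposure series the knots are taken from.
#' @param max_lag maximum lag in days.
#' @param var_percentiles percentiles for the exposure interior knots.
#' @param var_degree B-spline degree of the exposure basis.
#' @param lag_knots number of interior lag knots; default 2 when
#'   `max_lag <= 7`, else 3.
#' @return A [crossbasis_spec()].
#' @export
default_crossbasis_spec <- function(tmean, max_lag = 7L,
                                    var_percentiles = c(10, 75, 90),
                                    var_degree = 3L,
                                    lag_knots = NULL) {
  max_lag <- as.integer(max_lag)
  if (is.null(lag_knots)) lag_knots <- if (max_lag <= 7L) 2L else 3L
  vs <- basis_spec("bspline",
                   interior_knots = percentile_knots(tmean, var_percentiles),
                   boundary_knots = range(tmean, na.rm = TRUE),
                   degree = var_degree, intercept = FALSE)
  ls <- basis_spec("natural_cubic",
                   interior_knots = log_lag_knots(max_lag, lag_knots),
                   boundary_knots = c(0, max_lag),
                   intercept = TRUE)
  crossbasis_spec(vs, ls, max_lag)
}

# Lag basis evaluated exactly at the integer lags 0..L: (L+1) x lag_df.
lag_basis_matrix <- function(spec) {
  eval_basis(0:spec$max_lag, spec$lag_spec)
}

#' Build the DLNM cross-basis matrix
#'
#' Constructs the `n x (var_df * lag_df)` tensor-product design block from a
#' daily exposure series. Columns are ordered var-major: all lag columns for
#' exposure-basis column 1 first, then exposure-basis column 2, and so on
#' (names `v<j>.l<k>`). Rows with incomplete exposure history (the first
#' `max_lag` days, or windows containing a missing exposure) are `NA` and
#' are dropped from the likelihood by the fitter.
#'
#' @param x numeric exposure series (daily, in calendar order).
#' @param spec a [crossbasis_spec()].
#' @return An object of class `"crossbasis"`: the matrix plus `spec` and the
#'   source series as attributes.
#' @export
build_crossbasis <- function(x, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  x <- as.numeric(x)
  L <- spec$max_lag
  n <- length(x)
  if (n <= L) stop("exposure series must be longer than max_lag")
  vb <- eval_basis(x, spec$var_spec)          # n x var_df
  C <- lag_basis_matrix(spec)                 # (L+1) x lag_df
  vdf <- spec$var_spec$df
  ldf <- spec$lag_spec$df
  out <- matrix(NA_real_, n, vdf * ldf)
  # row t: sum over lags l of vb[t - l, j] * C[l + 1, k]
  for (j in seq_len(vdf)) {
    lagged <- matrix(NA_real_, n, L + 1L)
    for (l in 0:L) lagged[(1L + l):n, l + 1L] <- vb[1:(n - l), j]
    out[, (j - 1L) * ldf + seq_len(ldf)] <- lagged %*% C
  }
  colnames(out) <- as.vector(t(outer(seq_len(vdf), seq_len(ldf),
                                     function(j, k) sprintf("v%d.l%d", j, k))))
  structure(out, spec = spec, exposure = x, class = c("crossbasis", "matrix"))
}

#' Reduce full DLNM coefficients to the overall cumulative curve
#'
#' Sums the fitted exposure-lag surface over all lags, yielding the overall
#' cumulative exposure-response association on the log relative-risk scale.
#' The reduction is the linear map `M = I_vdf (x) colSums(lagbasis)` applied
#' to the var-major coefficient vector; the covariance transforms as
#' `M V M'`.
#'
#' @param coef_full fitted coefficient vector for the cross-basis block
#'   (length `var_df * lag_df`, var-major order).
#' @param vcov_full corresponding covariance matrix.
#' @param spec the [crossbasis_spec()] the coefficients belong to.
#' @return An object of class `"reduced_curve"` with elements `coef`
#'   (length `var_df`), `vcov`, `var_spec` and `center` (`NULL` until a
#'   reference temperature is chosen at prediction time).
#' @export
reduce_overall <- function(coef_full, vcov_full, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  vdf <- spec$var_spec$df
  ldf <- spec$lag_spec$df
  coef_full <- as.numeric(coef_full)
  if (length(coef_full) != vdf * ldf)
    stop("coef_full has length ", length(coef_full),
         ", expected var_df * lag_df = ", vdf * ldf)
  vcov_full <- as.matrix(vcov_full)
  if (!all(dim(vcov_full) == vdf * ldf))
    stop("vcov_full is not conformable with coef_full")
  u <- colSums(lag_basis_matrix(spec))        # length lag_df
  M <- kronecker(diag(vdf), matrix(u, nrow = 1L))
  structure(
    list(coef = drop(M %*% coef_full),
         vcov = M %*% vcov_full %*% t(M),
         var_spec = spec$var_spec,
         center = NULL),
    class = "reduced_curve")
}

#' @export
print.reduced_curve <- function(x, ...) {
  cat(sprintf("<reduced_curve> overall cumulative association, df = %d\n",
              length(x$coef)))
  cat("  coef:", paste(signif(x$coef, 4), collapse = ", "), "\n")
  if (!is.null(x$center)) cat("  centered at:", x$center, "\n")
  invisible(x)
}

#' Predict the overall cumulative exposure-response curve
#'
#' Evaluates a reduced curve on a grid, re-centered at a reference exposure
#' value: `logRR(v) = (b(v) - b(center))' coef`, with the standard error
#' from the matching quadratic form. The log relative risk is exactly zero
#' at the center. Curves can be re-centered at will (e.g. at the minimum
#' mortality temperature once it is known) because log-RR differences are
#' invariant to the centering used during fitting.
#'
#' @param curve a [reduce_overall()] result (or a BLUP curve).
#' @param grid numeric vector of exposure values.
#' @param center reference exposure value, inside the basis domain.
#' @param clamp passed to [eval_basis()]; clamp out-of-domain grid values to
#'   the boundary knots instead of raising an error.
#' @return data frame with columns `x`, `logrr`, `se`, `rr`, `rr_low`,
#'   `rr_high` (pointwise 95% Wald interval on the RR scale).
#' @export
predict_curve <- function(curve, grid, center, clamp = FALSE) {
  stopifnot(inherits(curve, "reduced_curve"))
  b <- eval_basis(grid, curve$var_spec, clamp = clamp)
  b0 <- eval_basis(center, curve$var_spec, clamp = clamp)
  d <- sweep(b, 2L, drop(b0))
  logrr <- drop(d %*% curve$coef)
  se <- sqrt(pmax(0, rowSums((d %*% curve$vcov) * d)))
  data.frame(x = as.numeric(grid), logrr = logrr, se = se,
             rr = exp(logrr),
             rr_low = exp(logrr - 1.959964 * se),
             rr_high = exp(logrr + 1.959964 * se))
}

#' Predict the lag-response curve at a fixed exposure value
#'
#' Lag-specific contribution to the log relative risk at `exposure_value`
#' relative to `center`, for each integer lag `0..max_lag` — the lag-response
#' curve for a given hot or cold temperature. Summing over lags reproduces
#' the overall cumulative prediction from the reduced curve.
#'
#' @param coef_full,vcov_full full cross-basis coefficients and covariance
#'   (var-major order, as fitted).
#' @param spec the [crossbasis_spec()].
#' @param exposure_value exposure at which the surface is sliced.
#' @param center reference exposure value.
#' @return data frame with columns `lag`, `logrr`, `se`, `rr`.
#' @export
predict_lag_surface <- function(coef_full, vcov_full, spec, exposure_value,
                                center) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  vdf <- spec$var_spec$df
  ldf <- spec$lag_spec$df
  coef_full <- as.numeric(coef_full)
  stopifnot(length(coef_full) == vdf * ldf)
  C <- lag_basis_matrix(spec)
  bv <- drop(eval_basis(exposure_value, spec$var_spec))
  b0 <- drop(eval_basis(center, spec$var_spec))
  d <- bv - b0                                 # length vdf
  # design row for lag l: var-major kron of d and C[l, ]
  D <- matrix(0, nrow(C), vdf * ldf)
  for (j in seq_len(vdf))
    D[, (j - 1L) * ldf + seq_len(ldf)] <- d[j] * C
  logrr <- drop(D %*% coef_full)
  se <- sqrt(pmax(0, rowSums((D %*% as.matrix(vcov_full)) * D)))
  data.frame(lag = 0:spec$max_lag, logrr = logrr, se = se, rr = exp(logrr))
}

#' Serialize / restore a reduced curve as delimited text
#'
#' Writes the curve (coefficients, covariance, basis knots, center) as a
#' small key-value text block so stage-2 and attribution inputs can be
#' exchanged as plain files.
#'
#' @param curve a `"reduced_curve"`.
#' @param path file path.
#' @return `read_reduced_curve()` returns the restored `"reduced_curve"`.
#' @export
write_reduced_curve <- function(curve, path) {
  stopifnot(inherits(curve, "reduced_curve"))
  sp <- curve$var_spec
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  lines <- c(
    paste0("family\t", sp$family),
    paste0("degree\t", sp$degree),
    paste0("intercept\t", as.integer(sp$intercept)),
    paste0("interior_knots\t", num(sp$interior_knots)),
    paste0("boundary_knots\t", num(sp$boundary_knots)),
    paste0("center\t", if (is.null(curve$center)) "NA" else num(curve$center)),
    paste0("coef\t", num(curve$coef)),
    paste0("vcov\t", num(as.vector(curve$vcov))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reduced_curve
#' @param path file path.
#' @export
read_reduced_curve <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  nums <- function(k) {
    v <- get(k)
    if (is.na(v) || identical(v, "NA") || !nzchar(v)) return(numeric(0))
    as.numeric(strsplit(trimws(v), "\\s+")[[1L]])
  }
  spec <- basis_spec(get("family"),
                     interior_knots = nums("interior_knots"),
                     boundary_knots = nums("boundary_knots"),
                     degree = as.integer(get("degree")),
                     intercept = as.integer(get("intercept")) == 1L)
  coef <- nums("coef")
  q <- length(coef)
  center <- nums("center")
  structure(list(coef = coef,
                 vcov = matrix(nums("vcov"), q, q),
                 var_spec = spec,
                 center = if (length(center)) center else NULL),
            class = "reduced_curve")
}
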