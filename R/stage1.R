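#' Daily mortality/exposure series for one location
#'
#' Validates and assembles the per-location input of the first-stage model:
#' consecutive calendar days with all-cause death counts, daily mean
#' temperature (degrees C), daily mean relative humidity (%) and optionally
#' daily mean PM2.5 (ug/m3). Missing values are allowed and marked `NA`;
#' date gaps are not (the lag structure needs the full calendar grid).
#'
#' @param location_id scalar identifier.
#' @param dates `Date` vector, consecutive calendar days.
#' @param deaths non-negative integer counts (`NA` allowed).
#' @param tmean,rh,pm25 numeric covariate series; `pm25` optional.
#' @return An object of class `"daily_series"` (a data frame).
#' @export
daily_series <- function(location_id, dates, deaths, tmean, rh, pm25 = NULL) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (n < 2L) stop("need at least two days")
  if (any(diff(as.integer(dates)) != 1L))
    stop("'dates' must be consecutive calendar days (mark missing data NA, ",
         "do not drop rows)")
  deaths <- as.numeric(deaths)
  if (any(deaths < 0 | deaths != floor(deaths), na.rm = TRUE))
    stop("'deaths' must be non-negative integers")
  lens <- c(length(deaths), length(tmean), length(rh),
            if (!is.null(pm25)) length(pm25))
  if (any(lens != n)) stop("all series must have the same length as 'dates'")
  out <- data.frame(date = dates, deaths = deaths,
                    tmean = as.numeric(tmean), rh = as.numeric(rh))
  if (!is.null(pm25)) out$pm25 <- as.numeric(pm25)
  attr(out, "location_id") <- location_id
  class(out) <- c("daily_series", "data.frame")
  out
}

#' First-stage model configuration
#'
#' @param max_lag maximum lag of the cross-basis, days.
#' @param season_df_per_year degrees of freedom per year of the natural cubic
#'   spline of time controlling seasonality and long-term trend (total df is
#'   `round(df_per_year * n_years)`).
#' @param var_percentiles,var_degree exposure-basis settings, see
#'   [default_crossbasis_spec()].
#' @param lag_knots number of interior lag knots (`NULL` = 2 for lag 0-7,
#'   3 beyond).
#' @param use_rh include a same-day linear relative-humidity term.
#' @param use_pm25 include a same-day linear PM2.5 term.
#' @return list of class `"stage1_config"`.
#' @export
stage1_config <- function(max_lag = 7L, season_df_per_year = 6,
                          var_percentiles = c(10, 75, 90), var_degree = 3L,
                          lag_knots = NULL, use_rh = TRUE, use_pm25 = FALSE) {
  structure(list(max_lag = as.integer(max_lag),
                 season_df_per_year = season_df_per_year,
                 var_percentiles = var_percentiles,
                 var_degree = as.integer(var_degree),
                 lag_knots = lag_knots,
                 use_rh = isTRUE(use_rh), use_pm25 = isTRUE(use_pm25)),
            class = "stage1_config")
}

#' Assemble the first-stage design matrix
#'
#' Columns: intercept; the DLNM cross-basis; a natural cubic spline of the
#' day index for seasonality and trend; six day-of-week indicators (Monday
#' is the reference); a linear relative-humidity term; optionally a linear
#' PM2.5 term. A column map records which columns belong to which block so
#' cross-basis coefficients can be extracted unambiguously.
#'
#' @param series a [daily_series()].
#' @param config a [stage1_config()].
#' @param cb_spec optional pre-built [crossbasis_spec()]; by default knots
#'   are placed from the location's own temperature distribution.
#' @return list with `X` (matrix), `blocks` (named list of column indices)
#'   and `cb_spec`.
#' @export
build_design <- function(series, config = stage1_config(), cb_spec = NULL) {
  stopifnot(inherits(series, "daily_series"))
  n <- nrow(series)
  if (all(is.na(series$tmean))) stop("temperature is entirely missing")
  if (config$use_rh && all(is.na(series$rh)))
    stop("relative humidity is entirely missing but use_rh = TRUE")
  if (config$use_pm25 && (is.null(series$pm25) || all(is.na(series$pm25))))
    stop("PM2.5 requested (use_pm25 = TRUE) but column 'pm25' is absent or ",
         "entirely missing")
  if (is.null(cb_spec))
    cb_spec <- default_crossbasis_spec(series$tmean, config$max_lag,
                                       config$var_percentiles,
                                       config$var_degree, config$lag_knots)
  cb <- build_crossbasis(series$tmean, cb_spec)

  n_years <- n / 365.25
  season_df <- max(1L, as.integer(round(config$season_df_per_year * n_years)))
  tspl <- unclass(splines::ns(seq_len(n), df = season_df))

  dow <- factor(format(series$date, "%u"), levels = as.character(1:7))  # 1 = Monday
  dowm <- stats::model.matrix(~ dow)[, -1L, drop = FALSE]

  parts <- list(intercept = matrix(1, n, 1L),
                crossbasis = unclass(cb),
                season = tspl,
                dow = dowm)
  if (config$use_rh) parts$rh <- matrix(series$rh, n, 1L)
  if (config$use_pm25) parts$pm25 <- matrix(series$pm25, n, 1L)

  X <- do.call(cbind, parts)
  idx <- 0L
  blocks <- lapply(parts, function(p) {
    cols <- idx + seq_len(ncol(p)); idx <<- idx + ncol(p); cols
  })
  colnames(X) <- unlist(mapply(function(nm, p) {
    if (ncol(p) == 1L) nm else paste0(nm, ".", seq_len(ncol(p)))
  }, names(parts), parts, SIMPLIFY = FALSE))
  list(X = X, blocks = blocks, cb_spec = cb_spec)
}

#' Quasi-Poisson fit by iteratively reweighted least squares
#'
#' Fits a log-link Poisson mean model; point estimates are the Poisson
#' maximum-likelihood estimates and the covariance is scaled by the Pearson
#' dispersion `phi = sum((y - mu)^2 / mu) / (n - p)`. Delegates the IRLS
#' iterations to [stats::glm.fit()] with a tightened convergence tolerance
#' (deviance change < 1e-10, at most 50 iterations).
#'
#' Rows with any missing value in `y` or `X` are dropped from the
#' likelihood. Rank deficiency is an error: the offending columns are named
#' so the design block responsible can be identified.
#'
#' @param y counts.
#' @param X design matrix (including the intercept column).
#' @param weights optional prior weights.
#' @return list with `coef`, `vcov` (phi-scaled), `vcov_unscaled`,
#'   `dispersion`, `iterations`, `converged`, `fitted`, `deviance`, `used`
#'   (logical row mask).
#' @export
fit_quasipoisson <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (is.null(weights)) weights <- rep(1, length(y))
  used <- !is.na(y) & stats::complete.cases(X)
  ys <- y[used]; Xs <- X[used, , drop = FALSE]; ws <- weights[used]
  p <- ncol(Xs)
  qrX <- qr(Xs)
  if (qrX$rank < p) {
    bad <- colnames(Xs)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm.fit(Xs, ys, weights = ws, family = stats::quasipoisson(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 50L))
  mu <- fit$fitted.values
  n_used <- length(ys)
  phi <- sum(ws * (ys - mu)^2 / mu) / (n_used - p)
  # unscaled covariance = inverse Fisher information at the final coefficients
  info <- crossprod(Xs, Xs * (ws * mu))
  cov_unscaled <- chol2inv(chol(info))
  dimnames(cov_unscaled) <- list(colnames(Xs), colnames(Xs))
  if (!fit$converged)
    warning("IRLS did not converge in ", fit$iter, " iterations")
  list(coef = fit$coefficients,
       vcov = phi * cov_unscaled,
       vcov_unscaled = cov_unscaled,
       dispersion = phi,
       iterations = fit$iter,
       converged = fit$converged,
       fitted = mu,
       deviance = fit$deviance,
       used = used)
}

#' Fit the first-stage model for one location
#'
#' Composes the full stage-1 pipeline for a location: percentile knots on
#' the location's own temperature distribution, cross-basis, design
#' assembly, quasi-Poisson fit, and reduction of the cross-basis
#' coefficients to the overall cumulative exposure-response curve. The
#' first `max_lag` days (incomplete exposure history) and any day with
#' missing data are excluded from the likelihood; lags are computed on the
#' calendar grid so histories are never silently shortened.
#'
#' The curve is fitted uncentred; re-centering (at the minimum mortality
#' temperature, once known) happens at prediction time, since log-RR
#' differences do not depend on the centering used during fitting.
#'
#' @param series a [daily_series()].
#' @param config a [stage1_config()].
#' @return An object of class `"stage1_fit"`: `location_id`, `coef_full`,
#'   `vcov_full` (cross-basis block, phi-scaled), `dispersion`, `reduced`
#'   (a `"reduced_curve"`), `cb_spec`, `percentile_table` (temperature at
#'   percentiles 1..99), `n_days_used`, `converged`, `iterations`,
#'   `total_deaths`.
#' @export
fit_location <- function(series, config = stage1_config()) {
  stopifnot(inherits(series, "daily_series"))
  des <- build_design(series, config)
  if (sum(stats::complete.cases(des$X) & !is.na(series$deaths)) < 365)
    stop("fewer than one year of usable days after lag trimming")
  fit <- fit_quasipoisson(series$deaths, des$X)
  cb_cols <- des$blocks$crossbasis
  coef_cb <- fit$coef[cb_cols]
  vcov_cb <- fit$vcov[cb_cols, cb_cols, drop = FALSE]
  reduced <- reduce_overall(coef_cb, vcov_cb, des$cb_spec)
  structure(
    list(location_id = attr(series, "location_id"),
         coef_full = coef_cb,
         vcov_full = vcov_cb,
         dispersion = fit$dispersion,
         reduced = reduced,
         cb_spec = des$cb_spec,
         percentile_table = percentile_table(series$tmean),
         n_days_used = sum(fit$used),
         converged = fit$converged,
         iterations = fit$iterations,
         total_deaths = sum(series$deaths, na.rm = TRUE)),
    class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("<stage1_fit> location %s: %d days used, dispersion %.3f%s\n",
              x$location_id, x$n_days_used, x$dispersion,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Empirical temperature percentile table
#'
#' Temperature at each integer percentile 1..99 of a location's observed
#' distribution (type-7 quantiles); the grid on which the minimum mortality
#' temperature is searched and attribution bands are cut.
#'
#' @param tmean numeric temperature series.
#' @return named numeric vector of length 99.
#' @export
percentile_table <- function(tmean) {
  percentile_knots(tmean, 1:99)
}

#' Read daily series from a delimited text file
#'
#' Reads either a single-location file or a long-format file with a
#' `location` column, with columns `date`, `deaths`, `tmean`, `rh` and
#' optionally `pm25`.
#'
#' @param path delimited text file (separator auto-detected from the
#'   header line among tab, comma, semicolon).
#' @return A list of [daily_series()] objects, named by location.
#' @export
read_daily_series <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- c("\t", ",", ";")[which.max(vapply(c("\t", ",", ";"), function(s)
    lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))), 1L))]
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("date", "deaths", "tmean", "rh")
  if (!all(need %in% names(d)))
    stop("input must have columns ", paste(need, collapse = ", "))
  split_col <- if ("location" %in% names(d)) d$location else "location_1"
  out <- lapply(split(d, split_col), function(g) {
    g <- g[order(as.Date(g$date)), ]
    daily_series(g$location[1L] %||% "location_1", g$date, g$deaths,
                 g$tmean, g$rh, if ("pm25" %in% names(g)) g$pm25)
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write daily series to a long-format delimited text file
#'
#' @param series_list list of [daily_series()] objects.
#' @param path output path (tab-separated).
#' @export
write_daily_series <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(location = attr(s, "location_id"), as.data.frame(s))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
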