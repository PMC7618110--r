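#' Find the minimum mortality temperature
#'
#' Evaluates an (uncentred) overall cumulative curve on a location's
#' empirical temperature percentile grid (percentiles 1..99) and returns the
#' temperature and percentile at which predicted mortality is lowest — the
#' reference ("optimum") temperature for attribution. Ties are broken toward
#' the median percentile. A monotone curve puts the minimum at percentile 1
#' or 99; such boundary solutions are flagged.
#'
#' @param curve a `"reduced_curve"` (typically a BLUP curve).
#' @param percentile_table temperature at percentiles 1..99, as from
#'   [percentile_table()].
#' @return list of class `"mmt_result"`: `mmt` (degrees C), `mmp`
#'   (percentile), `boundary` (logical flag), `search_grid`.
#' @export
find_mmt <- function(curve, percentile_table) {
  stopifnot(inherits(curve, "reduced_curve"), length(percentile_table) == 99L)
  b <- eval_basis(percentile_table, curve$var_spec, clamp = TRUE)
  val <- drop(b %*% curve$coef)
  best <- val <= min(val) + 1e-12
  cand <- which(best)
  mmp <- cand[which.min(abs(cand - 50L))]   # tie-break toward the median
  structure(list(mmt = unname(percentile_table[mmp]),
                 mmp = as.integer(mmp),
                 boundary = mmp %in% c(1L, 99L),
                 search_grid = percentile_table),
            class = "mmt_result")
}

#' @export
print.mmt_result <- function(x, ...) {
  cat(sprintf("<mmt_result> MMT %.2f degC at percentile %d%s\n", x$mmt, x$mmp,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

# Backward moving average over the lag window 0..L, column-wise for
# matrices; NA while the history is incomplete.
lag_window_mean <- function(x, max_lag) {
  if (max_lag == 0L) return(x)
  out <- stats::filter(x, rep(1 / (max_lag + 1L), max_lag + 1L),
                       sides = 1)
  if (is.matrix(x)) matrix(as.numeric(out), nrow(x), ncol(x))
  else as.numeric(out)
}

#' Daily attributable deaths (backward attribution)
#'
#' For each day `t`, the cumulative log relative risk of the day's exposure
#' history relative to the minimum mortality temperature is converted into
#' an attributable number of deaths `AN_t = deaths_t * (1 - exp(-eta_t))`.
#' Stage 2 pools only the reduced (overall cumulative) curve `f`, so the
#' per-lag surface is not available; the cumulative log-RR of the history
#' is reconstructed by allocating `f` uniformly over the window,
#' `eta_t = mean over l in 0..L of f(x[t - l])`. Summed over the series
#' this reproduces the true cumulative contribution for any lag-weight
#' profile that sums to one, whereas evaluating `f` at the window-mean
#' exposure would be biased downward for convex curves. Days with
#' incomplete history (the first `L` of the series, or windows containing
#' a missing exposure) contribute 0 and are counted. Negative `eta` (the
#' protective side of the curve) yields negative attributable numbers.
#'
#' @param series a [daily_series()].
#' @param curve the location's `"reduced_curve"` (typically its BLUP).
#' @param mmt minimum mortality temperature, inside the curve domain.
#' @param max_lag lag window of the analysis, days.
#' @param coef optional replacement coefficient vector (used by the
#'   Monte-Carlo confidence-interval machinery).
#' @return data frame with `date`, `deaths`, `tmean`, `eta`, `an`,
#'   `complete` (history flag).
#' @export
attributable_series <- function(series, curve, mmt, max_lag,
                                coef = curve$coef) {
  stopifnot(inherits(series, "daily_series"), inherits(curve, "reduced_curve"))
  rng <- curve$var_spec$boundary_knots
  if (mmt < rng[1L] || mmt > rng[2L])
    stop("mmt lies outside the curve's basis domain [", rng[1L], ", ",
         rng[2L], "]")
  b <- eval_basis(series$tmean, curve$var_spec, clamp = TRUE)
  b0 <- eval_basis(mmt, curve$var_spec)
  f_day <- drop(sweep(b, 2L, drop(b0)) %*% coef)   # overall curve per day
  eta <- lag_window_mean(f_day, max_lag)
  complete <- !is.na(eta)
  an <- series$deaths * (1 - exp(-eta))
  an[!complete | is.na(series$deaths)] <- 0
  data.frame(date = series$date, deaths = series$deaths,
             tmean = series$tmean, eta = eta, an = an, complete = complete)
}

# Category masks over days: total / cold / heat / percentile bands, cut on
# the day's own mean temperature. Days exactly at the MMT fall in neither
# cold nor heat.
attribution_masks <- function(tmean, mmt, percentile_table) {
  pt <- percentile_table
  list(total = rep(TRUE, length(tmean)),
       cold = !is.na(tmean) & tmean < mmt,
       heat = !is.na(tmean) & tmean > mmt,
       p1  = !is.na(tmean) & tmean < pt[1L]  & tmean < mmt,
       p5  = !is.na(tmean) & tmean < pt[5L]  & tmean < mmt,
       p10 = !is.na(tmean) & tmean < pt[10L] & tmean < mmt,
       p90 = !is.na(tmean) & tmean > pt[90L] & tmean > mmt,
       p95 = !is.na(tmean) & tmean > pt[95L] & tmean > mmt,
       p99 = !is.na(tmean) & tmean > pt[99L] & tmean > mmt)
}

#' Attributable deaths and fractions with empirical confidence intervals
#'
#' Splits the daily attributable numbers into categories — total, cold
#' (days below the MMT), heat (days above), and extreme-percentile bands
#' (below the 1st/5th/10th and above the 90th/95th/99th percentile of the
#' location's temperature distribution) — and reports attributable numbers
#' (AN) and attributable fractions (AF, % of all deaths) for each.
#' Confidence intervals are empirical: `n_sim` coefficient vectors are
#' drawn from the multivariate normal distribution of the curve
#' coefficients and the full attribution is recomputed for each draw; the
#' 2.5th and 97.5th percentiles of the simulated totals bound the interval.
#' `AN_total = AN_cold + AN_heat` holds exactly, for the point estimates
#' and for every draw.
#'
#' @param series a [daily_series()].
#' @param curve the location's `"reduced_curve"` (typically its BLUP).
#' @param mmt minimum mortality temperature.
#' @param max_lag lag window, days.
#' @param percentile_table temperature at percentiles 1..99.
#' @param n_sim number of Monte-Carlo draws (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed integer seed for the draws (mandatory, for reproducibility).
#' @return An object of class `"attribution_result"`: a data frame with one
#'   row per category and columns `category`, `an`, `an_low`, `an_high`,
#'   `af`, `af_low`, `af_high`, `days`; attributes `total_deaths`, `n_sim`,
#'   `seed`, `mmt`.
#' @export
summarize_attribution <- function(series, curve, mmt, max_lag,
                                  percentile_table, n_sim = 1000L,
                                  seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  n_sim <- as.integer(n_sim)
  if (n_sim < 100L) warning("n_sim < 100 gives unstable empirical intervals")
  das <- attributable_series(series, curve, mmt, max_lag)
  masks <- attribution_masks(das$tmean, mmt, percentile_table)
  total_deaths <- sum(series$deaths, na.rm = TRUE)
  point <- vapply(masks, function(m) sum(das$an[m]), 0)

  # Monte-Carlo draws of the coefficient vector through the full attribution;
  # the centered basis is fixed across draws, so eta is a single matrix product
  set.seed(seed)
  draws <- mvrnorm_draws(n_sim, curve$coef, curve$vcov)
  D <- sweep(eval_basis(series$tmean, curve$var_spec, clamp = TRUE), 2L,
             drop(eval_basis(mmt, curve$var_spec)))
  eta_sim <- lag_window_mean(D %*% t(draws), max_lag)        # n x n_sim
  an_sim <- series$deaths * (1 - exp(-eta_sim))
  an_sim[!das$complete | is.na(series$deaths), ] <- 0
  M <- vapply(masks, as.numeric, numeric(nrow(das)))         # n x categories
  sims <- crossprod(an_sim, M)                               # n_sim x categories

  ci <- apply(sims, 2L, stats::quantile, probs = c(0.025, 0.975), type = 7)
  out <- data.frame(category = names(masks),
                    an = unname(point),
                    an_low = ci[1L, ], an_high = ci[2L, ],
                    af = 100 * unname(point) / total_deaths,
                    af_low = 100 * ci[1L, ] / total_deaths,
                    af_high = 100 * ci[2L, ] / total_deaths,
                    days = vapply(masks, sum, 0L),
                    row.names = NULL)
  structure(out, class = c("attribution_result", "data.frame"),
            total_deaths = total_deaths, n_sim = n_sim, seed = seed,
            mmt = mmt, sims = sims)
}

# Multivariate normal draws via the eigendecomposition (tolerates PSD vcov).
mvrnorm_draws <- function(n, mu, Sigma) {
  q <- length(mu)
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * q), n, q)
  sweep(Z %*% t(e$vectors %*% diag(sqrt(ev), q)), 2L, mu, `+`)
}

#' Aggregate attribution results across locations
#'
#' Country-level attributable numbers are sums over locations; fractions
#' use the summed deaths. Confidence intervals sum the per-location
#' Monte-Carlo draws (independent across locations) and take empirical
#' percentiles of the summed totals, so all locations must have been
#' summarized with the same `n_sim`.
#'
#' @param results list of `"attribution_result"` objects.
#' @return An `"attribution_result"` for the aggregate.
#' @export
aggregate_attribution <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "attribution_result")))
  n_sim <- unique(vapply(results, attr, 0L, "n_sim"))
  if (length(n_sim) != 1L)
    stop("all locations must use the same n_sim to aggregate intervals")
  total_deaths <- sum(vapply(results, attr, 0, "total_deaths"))
  point <- Reduce(`+`, lapply(results, function(r) r$an))
  days <- Reduce(`+`, lapply(results, function(r) r$days))
  sims <- Reduce(`+`, lapply(results, function(r) attr(r, "sims")))
  ci <- apply(sims, 2L, stats::quantile, probs = c(0.025, 0.975), type = 7)
  out <- data.frame(category = results[[1L]]$category,
                    an = point,
                    an_low = ci[1L, ], an_high = ci[2L, ],
                    af = 100 * point / total_deaths,
                    af_low = 100 * ci[1L, ] / total_deaths,
                    af_high = 100 * ci[2L, ] / total_deaths,
                    days = days, row.names = NULL)
  structure(out, class = c("attribution_result", "data.frame"),
            total_deaths = total_deaths, n_sim = n_sim, seed = NA_integer_,
            mmt = NA_real_, sims = sims)
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s deaths, n_sim = %d\n",
              format(attr(x, "total_deaths"), big.mark = ","),
              attr(x, "n_sim")))
  df <- as.data.frame(x)
  df$an <- round(df$an); df$an_low <- round(df$an_low)
  df$an_high <- round(df$an_high)
  df$af <- round(df$af, 2); df$af_low <- round(df$af_low, 2)
  df$af_high <- round(df$af_high, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
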