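#' Configuration of a full two-stage run
#'
#' Validated, serializable bundle of every modelling choice: lag window,
#' seasonality df per year, exposure-spline settings, lag-knot rule,
#' covariate toggles, optional period stratum, Monte-Carlo settings.
#'
#' @param max_lag lag window in days (7, 14, 21 or 28 in the standard
#'   sensitivity grid; any positive value accepted).
#' @param season_df_per_year seasonality spline df per year (4, 6 or 8 in
#'   the standard grid).
#' @param var_degree exposure B-spline degree.
#' @param var_percentiles exposure interior-knot percentiles.
#' @param lag_knots interior lag-knot count; `NULL` applies the rule
#'   2 knots for lag 0-7, 3 knots for longer windows.
#' @param use_rh,use_pm25 covariate toggles.
#' @param period `NULL` or `c(first, last)` calendar years defining a
#'   stratum.
#' @param n_sim Monte-Carlo draws for empirical intervals.
#' @param seed integer seed (mandatory).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(max_lag = 7L, season_df_per_year = 6,
                       var_degree = 3L, var_percentiles = c(10, 75, 90),
                       lag_knots = NULL, use_rh = TRUE, use_pm25 = FALSE,
                       period = NULL, n_sim = 1000L, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0")
  if (season_df_per_year <= 0) stop("season_df_per_year must be positive")
  if (!is.null(period) && (length(period) != 2L || period[1] > period[2]))
    stop("period must be c(first_year, last_year)")
  structure(list(max_lag = max_lag,
                 season_df_per_year = season_df_per_year,
                 var_degree = as.integer(var_degree),
                 var_percentiles = var_percentiles,
                 lag_knots = lag_knots,
                 use_rh = isTRUE(use_rh), use_pm25 = isTRUE(use_pm25),
                 period = period,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "run_config")
}

as_stage1_config <- function(config) {
  stage1_config(max_lag = config$max_lag,
                season_df_per_year = config$season_df_per_year,
                var_percentiles = config$var_percentiles,
                var_degree = config$var_degree,
                lag_knots = config$lag_knots,
                use_rh = config$use_rh, use_pm25 = config$use_pm25)
}

subset_period <- function(series, period) {
  if (is.null(period)) return(series)
  yr <- as.integer(format(series$date, "%Y"))
  keep <- yr >= period[1] & yr <= period[2]
  out <- series[keep, , drop = FALSE]
  attr(out, "location_id") <- attr(series, "location_id")
  class(out) <- class(series)
  out
}

#' Run the full two-stage analysis
#'
#' Per-location first-stage fits, multivariate meta-regression, BLUPs,
#' minimum-mortality-temperature search, and cold/heat attribution with
#' empirical intervals, plus the country aggregate. Locations whose
#' first-stage fit fails are reported and excluded from stage 2 with a
#' warning; fewer than three usable locations aborts.
#'
#' @param series_list list of [daily_series()] objects.
#' @param meta_predictors data frame of location covariates (one row per
#'   location, same order), or `NULL` for intercept-only pooling.
#' @param config a [run_config()].
#' @return list of class `"result_bundle"`: `fits`, `meta`, `blups`,
#'   `mmt` (list of `"mmt_result"`), `attribution` (per location),
#'   `country` (aggregate `"attribution_result"`), `location_table`,
#'   `country_table`, `failed` (named character vector of error messages),
#'   `config`.
#' @export
run_two_stage <- function(series_list, meta_predictors = NULL, config) {
  stopifnot(inherits(config, "run_config"))
  s1cfg <- as_stage1_config(config)
  series_list <- lapply(series_list, subset_period, config$period)

  fits <- vector("list", length(series_list))
  failed <- character(0)
  for (i in seq_along(series_list)) {
    fits[[i]] <- tryCatch(fit_location(series_list[[i]], s1cfg),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) {
      id <- as.character(attr(series_list[[i]], "location_id"))
      failed[id] <- conditionMessage(fits[[i]])
    }
  }
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (length(failed))
    warning(length(failed), " location(s) failed stage 1 and were excluded: ",
            paste(names(failed), collapse = ", "))
  if (sum(ok) < 3L)
    stop("fewer than 3 locations fitted successfully; aborting stage 2",
         if (length(failed)) paste0(" (first failure: ", failed[1L], ")"))
  fits <- fits[ok]
  series_list <- series_list[ok]
  meta_ok <- if (is.null(meta_predictors)) NULL else
    meta_predictors[ok, , drop = FALSE]

  inp <- meta_input(fits, meta_ok)
  meta <- fit_meta(inp)
  blups <- blup(meta, inp, fits)

  k <- length(fits)
  mmt <- vector("list", k)
  att <- vector("list", k)
  for (i in seq_len(k)) {
    pt <- fits[[i]]$percentile_table
    mmt[[i]] <- find_mmt(blups[[i]]$curve, pt)
    att[[i]] <- summarize_attribution(series_list[[i]], blups[[i]]$curve,
                                      mmt[[i]]$mmt, config$max_lag, pt,
                                      n_sim = config$n_sim,
                                      seed = config$seed + i)
  }
  ids <- vapply(fits, function(f) as.character(f$location_id), "")
  names(mmt) <- names(att) <- ids
  country <- aggregate_attribution(att)

  loc_tab <- do.call(rbind, lapply(seq_len(k), function(i) {
    a <- att[[i]]
    row <- function(cat, col) a[[col]][a$category == cat]
    data.frame(location = ids[i],
               mmt = mmt[[i]]$mmt, mmp = mmt[[i]]$mmp,
               boundary_mmp = mmt[[i]]$boundary,
               an_total = row("total", "an"),
               an_cold = row("cold", "an"), an_heat = row("heat", "an"),
               af_total = row("total", "af"),
               af_cold = row("cold", "af"), af_heat = row("heat", "af"),
               total_deaths = attr(a, "total_deaths"),
               dispersion = fits[[i]]$dispersion,
               converged = fits[[i]]$converged)
  }))
  structure(list(fits = fits, meta = meta, blups = blups, mmt = mmt,
                 attribution = att, country = country,
                 location_table = loc_tab,
                 country_table = as.data.frame(country),
                 failed = failed, config = config),
            class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> %d locations, lag 0-%d\n",
              nrow(x$location_table), x$config$max_lag))
  cat(sprintf("  I2 = %.1f%% | country AF total %.2f%% (cold %.2f%%, heat %.2f%%)\n",
              x$meta$I2,
              x$country$af[x$country$category == "total"],
              x$country$af[x$country$category == "cold"],
              x$country$af[x$country$category == "heat"]))
  invisible(x)
}

#' Sensitivity grid over modelling choices
#'
#' Re-runs the full two-stage analysis over the Cartesian product of the
#' requested axes (e.g. `max_lag = c(7, 14, 21, 28)`,
#' `season_df_per_year = c(4, 6, 8)`, `use_pm25 = c(FALSE, TRUE)`) and
#' tabulates the country attributable fractions per variant. A failing
#' cell is recorded with its error message; the grid continues.
#'
#' @param series_list,meta_predictors,config as in [run_two_stage()].
#' @param axes named list of values per config field.
#' @return data frame with one row per variant: the axis values,
#'   `af_total`, `af_cold`, `af_heat` (+ `_low`/`_high` bounds) and
#'   `error` (`NA` when the cell succeeded).
#' @export
sensitivity_grid <- function(series_list, meta_predictors = NULL, config,
                             axes) {
  stopifnot(inherits(config, "run_config"), is.list(axes),
            length(names(axes)) == length(axes))
  bad <- setdiff(names(axes), names(config))
  if (length(bad)) stop("unknown config field(s) in axes: ",
                        paste(bad, collapse = ", "))
  grid <- expand.grid(axes, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    for (nm in names(axes)) cfg[[nm]] <- grid[[nm]][r]
    res <- tryCatch(run_two_stage(series_list, meta_predictors, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out[[r]] <- cbind(grid[r, , drop = FALSE],
                        data.frame(af_total = NA_real_, af_cold = NA_real_,
                                   af_heat = NA_real_,
                                   af_total_low = NA_real_,
                                   af_total_high = NA_real_,
                                   error = conditionMessage(res)))
    } else {
      ct <- res$country
      g <- function(cat, col) ct[[col]][ct$category == cat]
      out[[r]] <- cbind(grid[r, , drop = FALSE],
                        data.frame(af_total = g("total", "af"),
                                   af_cold = g("cold", "af"),
                                   af_heat = g("heat", "af"),
                                   af_total_low = g("total", "af_low"),
                                   af_total_high = g("total", "af_high"),
                                   error = NA_character_))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the result bundle as delimited text tables
#'
#' Emits `location_table.tsv` (per-location MMT/MMP and cold/heat burden,
#' the per-department table shape), `country_table.tsv` (category-level
#' attributable numbers and fractions, the headline table shape),
#' `pooled_curve.tsv` (fixed-effect pooled curve coefficients),
#' `blup_<id>.txt` reduced-curve files, and `config.txt`.
#'
#' @param bundle a [run_two_stage()] result.
#' @param dir output directory (created if needed).
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(bundle$location_table, "location_table.tsv")
  wt(bundle$country_table, "country_table.tsv")
  for (id in names(bundle$blups))
    write_reduced_curve(bundle$blups[[id]]$curve,
                        file.path(dir, paste0("blup_", id, ".txt")))
  cfg <- bundle$config
  lines <- vapply(names(cfg), function(nm)
    paste0(nm, "\t", paste(format(cfg[[nm]], digits = 17), collapse = " ")),
    "")
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
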