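#' Relative humidity from temperature and dewpoint
#'
#' August-Roche-Magnus approximation of the saturation vapor pressure,
#' `es(T) = exp(a T / (b + T))` up to a common factor, giving
#' `RH = 100 * exp(a td / (b + td)) / exp(a t / (b + t))`, clipped to
#' `[0, 100]`. The constants default to a widely used Magnus
#' parameterization, `a = 17.625` and `b = 243.04` degrees C.
#'
#' @param t air temperature, degrees C.
#' @param td dewpoint temperature, degrees C.
#' @param a,b Magnus coefficients (`a` dimensionless, `b` in degrees C).
#' @return relative humidity in percent, same length as the inputs.
#' @examples
#' rh_magnus(25, 20)  # 73.80
#' @export
rh_magnus <- function(t, td, a = 17.625, b = 243.04) {
  t <- as.numeric(t); td <- as.numeric(td)
  if (any(!is.finite(t)) || any(!is.finite(td)))
    stop("inputs must be finite")
  if (any(t <= -b) || any(td <= -b))
    stop("temperatures at or below ", -b,
         " degC hit the Magnus formula singularity")
  rh <- 100 * exp(a * td / (b + td)) / exp(a * t / (b + t))
  pmin(100, pmax(0, rh))
}

#' Aggregate hourly temperature/dewpoint records to daily means
#'
#' Derives the analysis-ready daily series from hourly (UTC) records:
#' relative humidity is computed pointwise with [rh_magnus()] and then
#' averaged — not computed from daily-mean temperature and dewpoint, which
#' differs because the formula is non-linear — and calendar days are
#' defined after shifting timestamps by a fixed UTC offset (-5 for
#' Colombia). Days observed for less than `min_coverage` of their expected
#' hours are flagged missing (`NA` means).
#'
#' @param timestamps `POSIXct` timestamps in UTC, regular cadence.
#' @param t2m air temperature, degrees C.
#' @param d2m dewpoint temperature, degrees C.
#' @param utc_offset offset in hours defining local calendar days
#'   (default -5).
#' @param min_coverage minimum fraction of expected records per day
#'   (default 0.75).
#' @return data frame with `date` (local calendar day), `tmean`, `rh`,
#'   `n_hours`, `complete`. Dewpoint above air temperature is physically
#'   unexpected and is flagged with a warning, not an error.
#' @export
daily_aggregate <- function(timestamps, t2m, d2m, utc_offset = -5,
                            min_coverage = 0.75) {
  if (!inherits(timestamps, "POSIXct")) stop("'timestamps' must be POSIXct")
  n <- length(timestamps)
  if (n == 0L) stop("empty hourly series")
  stopifnot(length(t2m) == n, length(d2m) == n)
  if (any(d2m > t2m + 1e-9, na.rm = TRUE))
    warning(sum(d2m > t2m + 1e-9, na.rm = TRUE),
            " records have dewpoint above air temperature")
  local <- timestamps + utc_offset * 3600
  day <- as.Date(local, tz = "UTC")
  rh <- rh_magnus(t2m, pmin(d2m, t2m))
  cadence <- if (n > 1L)
    stats::median(as.numeric(diff(sort(unique(timestamps))), units = "hours"))
  else 1
  expected <- max(1, round(24 / cadence))
  agg <- data.frame(date = sort(unique(day)))
  idx <- split(seq_len(n), day)
  agg$tmean <- vapply(idx, function(i) mean(t2m[i]), 0)
  agg$rh <- vapply(idx, function(i) mean(rh[i]), 0)
  agg$n_hours <- vapply(idx, length, 0L)
  agg$complete <- agg$n_hours >= min_coverage * expected
  agg$tmean[!agg$complete] <- NA_real_
  agg$rh[!agg$complete] <- NA_real_
  rownames(agg) <- NULL
  agg
}

#' Read a long-format hourly file
#'
#' Loader for pre-extracted hourly records: a delimited text file with
#' columns `timestamp` (ISO 8601, UTC), `t2m` and `d2m` in degrees C, and
#' optionally `location`. Spatial extraction from gridded reanalysis
#' (area-averaging over administrative polygons) is expected to have
#' happened upstream and is out of scope here.
#'
#' @param path file path (tab- or comma-separated, auto-detected).
#' @return list per location of data frames with `timestamps`, `t2m`, `d2m`.
#' @export
read_hourly <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("timestamp", "t2m", "d2m")
  if (!all(need %in% names(d)))
    stop("hourly input must have columns ", paste(need, collapse = ", "))
  ts <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  grp <- if ("location" %in% names(d)) d$location else "location_1"
  lapply(split(seq_len(nrow(d)), grp), function(i)
    data.frame(timestamps = ts[i], t2m = d$t2m[i], d2m = d$d2m[i]))
}
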