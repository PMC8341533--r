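#' Construct a univariate time series
#'
#' The basic container used throughout emmod: a named, ordered set of
#' (decimal-year time, value) pairs. Missing values (`NA`) mark gaps, e.g.
#' months at which a monitoring station did not report.
#'
#' @param times Numeric vector of strictly increasing timestamps in decimal
#'   years (month-start convention: January 1973 is `1973.0`, February
#'   `1973 + 1/12`, ...).
#' @param values Numeric vector of measurements, same length as `times`;
#'   `NA` marks a gap.
#' @param name Label for the series (used in printed output and CCM
#'   direction labels).
#' @param units Optional unit string carried as metadata (e.g. `"mg/L"`).
#' @return An object of class `emm_series`.
#' @export
emm_series <- function(times, values, name = "series", units = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) == 0L) {
    stop("empty input: a series needs at least one observation", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("`times` must be finite and non-missing", call. = FALSE)
  }
  d <- diff(times)
  if (any(d <= 0)) {
    bad <- times[which(d <= 0)[1] + 1L]
    stop(sprintf("times must be strictly increasing; violation at t = %.6f", bad),
         call. = FALSE)
  }
  structure(
    list(name = as.character(name)[1], times = times, values = values,
         units = units),
    class = "emm_series"
  )
}

#' @export
print.emm_series <- function(x, ...) {
  n <- length(x$times)
  ngap <- sum(is.na(x$values))
  cat(sprintf("<emm_series> %s: %d points, %.4f..%.4f%s%s\n",
              x$name, n, x$times[1], x$times[n],
              if (ngap > 0) sprintf(", %d gaps", ngap) else "",
              if (!is.null(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.emm_series <- function(x) length(x$times)

#' @export
as.data.frame.emm_series <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

is_emm_series <- function(x) inherits(x, "emm_series")

assert_series <- function(x, arg = deparse(substitute(x))) {
  if (!is_emm_series(x)) {
    stop(sprintf("`%s` must be an emm_series (see emm_series())", arg),
         call. = FALSE)
  }
  invisible(x)
}

#' Bundle station records of one measurand
#'
#' @param stations A list of [emm_series()] objects sharing one measurand.
#'   Stations may have gaps and unequal time supports.
#' @param station_ids Optional character labels; defaults to the series names.
#' @return An object of class `emm_station_set`.
#' @export
emm_station_set <- function(stations, station_ids = NULL) {
  if (!is.list(stations) || length(stations) == 0L) {
    stop("`stations` must be a non-empty list of emm_series", call. = FALSE)
  }
  for (s in stations) assert_series(s, "stations[[i]]")
  if (is.null(station_ids)) {
    station_ids <- vapply(stations, function(s) s$name, character(1))
  }
  structure(list(stations = stations, station_ids = as.character(station_ids)),
            class = "emm_station_set")
}

#' @export
print.emm_station_set <- function(x, ...) {
  cat(sprintf("<emm_station_set> %d stations: %s\n", length(x$stations),
              paste(x$station_ids, collapse = ", ")))
  invisible(x)
}

## ---- date handling ---------------------------------------------------------

#' Convert calendar dates to decimal years
#'
#' Month-start convention: `"1973-01"` (or `1973-01-01`) maps to `1973.0` and
#' each month adds `1/12`. Full dates keep sub-monthly resolution via the
#' day-of-month fraction so that jittered station sampling dates survive the
#' conversion.
#'
#' @param x Character vector of `YYYY-MM` or ISO-8601 `YYYY-MM-DD` dates.
#' @return Numeric vector of decimal years.
#' @export
decimal_year <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  ym <- grepl("^\\d{4}-\\d{2}$", x)
  out[ym] <- as.numeric(substr(x[ym], 1, 4)) +
    (as.numeric(substr(x[ym], 6, 7)) - 1) / 12
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y-%m-%d")
    if (anyNA(d)) {
      stop(sprintf("unparseable date: '%s'", x[full][which(is.na(d))[1]]),
           call. = FALSE)
    }
    lt <- as.POSIXlt(d)
    year <- lt$year + 1900
    month <- lt$mon              # 0-based
    dom <- lt$mday               # 1-based
    mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month + 1]
    leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
    mdays[month == 1 & leap] <- 29
    out[full] <- year + (month + (dom - 1) / mdays) / 12
  }
  bad <- !ym & !full
  if (any(bad)) {
    stop(sprintf("unparseable date: '%s' (expected YYYY-MM or YYYY-MM-DD)",
                 x[bad][1]), call. = FALSE)
  }
  out
}

#' Read a univariate time series from CSV
#'
#' Expects a header row (RFC-4180 quoting), one date column (`YYYY-MM` or
#' ISO-8601) and one numeric value column. Blank value cells become explicit
#' gaps (`NA`); rows are sorted by time.
#'
#' @param path Path to a CSV file.
#' @param date_column,value_column Column names (defaults `"date"`, `"value"`).
#' @param name Series label; defaults to the file name.
#' @param units Optional unit metadata.
#' @return An [emm_series()].
#' @export
read_timeseries_csv <- function(path, date_column = "date",
                                value_column = "value",
                                name = NULL, units = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  for (col in c(date_column, value_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
    }
  }
  if (nrow(df) == 0L) stop(sprintf("empty input: no rows in %s", path), call. = FALSE)
  times <- decimal_year(df[[date_column]])
  raw <- trimws(df[[value_column]])
  values <- suppressWarnings(as.numeric(raw))
  nonblank <- !(raw == "" | is.na(raw))
  if (any(nonblank & is.na(values))) {
    stop(sprintf("non-numeric value '%s' in column '%s'",
                 raw[nonblank & is.na(values)][1], value_column), call. = FALSE)
  }
  if (sum(!is.na(values)) == 0L) {
    stop(sprintf("empty input: zero valid rows in %s", path), call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]; values <- values[ord]
  dup <- duplicated(times)
  if (any(dup)) {
    stop(sprintf("duplicated timestamp: %s (decimal year %.6f)",
                 df[[date_column]][ord][dup][1], times[dup][1]), call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  emm_series(times, values, name = name, units = units)
}

#' Write a series as CSV
#'
#' `style = "time"` writes columns `time` (decimal year, 6 decimals) and
#' `value`; `style = "date"` writes `date` (ISO `YYYY-MM-DD`, the inverse of
#' [decimal_year()]) and `value`, the dialect [read_timeseries_csv()]
#' consumes. Values are printed with 9 significant digits so repeated runs
#' are byte-identical.
#'
#' @param ts An [emm_series()].
#' @param path Output path.
#' @param style Output dialect, `"time"` (default) or `"date"`.
#' @export
write_timeseries_csv <- function(ts, path, style = c("time", "date")) {
  assert_series(ts)
  style <- match.arg(style)
  if (style == "time") {
    lines <- c("time,value",
               sprintf("%.6f,%s", ts$times, fmt_num(ts$values)))
  } else {
    lines <- c("date,value",
               sprintf("%s,%s", format_month_date(ts$times), fmt_num(ts$values)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Convert decimal years back to ISO dates
#'
#' Inverse of [decimal_year()] under the month-start convention, to day
#' resolution.
#'
#' @param times Numeric vector of decimal years.
#' @return Character vector of `YYYY-MM-DD` dates.
#' @export
format_month_date <- function(times) {
  vapply(times, function(t) {
    year <- floor(t + 1e-9)
    m <- (t - year) * 12
    month <- floor(m + 1e-6)
    if (month >= 12) { month <- 0; year <- year + 1 }
    f <- m - month
    dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month + 1]
    if (month == 1 && ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0)) {
      dm <- 29
    }
    day <- min(dm, 1 + floor(f * dm + 0.5))
    sprintf("%04d-%02d-%02d", year, month + 1, day)
  }, character(1))
}

fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- ""
  out
}

## ---- regularization & summaries -------------------------------------------

#' Monthly decimal-year grid
#'
#' @param start_year Decimal year of the first grid point.
#' @param n_months Number of monthly points.
#' @return Numeric vector `start_year + (0:(n_months-1))/12`.
#' @export
monthly_grid <- function(start_year, n_months) {
  start_year + (seq_len(n_months) - 1L) / 12
}

#' Average multiple station records
#'
#' At each time present in any station, the mean over stations reporting
#' (non-gap) at that time; times where no station reports are omitted. The
#' result generally remains irregular and is regularized afterwards with
#' [regularize_to_grid()] — gaps inside stations are not interpolated here.
#'
#' @param stations An [emm_station_set()].
#' @param name Label for the averaged series.
#' @param bin `"none"` (default) averages at each exact time present in any
#'   station; `"month"` first pools all station samples falling in the same
#'   calendar month (value = their mean, time = their mean time). Monthly
#'   binning stabilizes the later spline regularization when sampling dates
#'   are jittered sub-monthly, and reduces to exact-time averaging when all
#'   samples sit on the monthly grid.
#' @return An [emm_series()].
#' @export
station_average <- function(stations, name = "station_average",
                            bin = c("none", "month")) {
  if (!inherits(stations, "emm_station_set")) {
    stop("`stations` must be an emm_station_set", call. = FALSE)
  }
  bin <- match.arg(bin)
  all_times <- sort(unique(unlist(lapply(stations$stations, function(s) s$times))))
  sums <- numeric(length(all_times))
  counts <- integer(length(all_times))
  for (s in stations$stations) {
    ok <- !is.na(s$values)
    idx <- match(s$times[ok], all_times)
    sums[idx] <- sums[idx] + s$values[ok]
    counts[idx] <- counts[idx] + 1L
  }
  keep <- counts > 0L
  if (!any(keep)) stop("no station reports at any time", call. = FALSE)
  units <- stations$stations[[1]]$units
  tt <- all_times[keep]
  vv <- sums[keep] / counts[keep]
  ww <- counts[keep]
  if (bin == "month") {
    grp <- floor(tt * 12 + 1e-9)
    tt2 <- as.numeric(tapply(tt * ww, grp, sum) / tapply(ww, grp, sum))
    vv2 <- as.numeric(tapply(vv * ww, grp, sum) / tapply(ww, grp, sum))
    ord <- order(tt2)
    tt <- tt2[ord]; vv <- vv2[ord]
  }
  emm_series(tt, vv, name = name, units = units)
}

#' Interpolate a series onto a uniform monthly grid
#'
#' Natural cubic-spline interpolation evaluated at the grid times, mirroring
#' the standard regularization of irregular station records onto the monthly
#' dates of a reference series. The interpolant passes exactly through
#' observations that coincide with grid points. The grid is trimmed to the
#' data support (no extrapolation); trimming emits a warning.
#'
#' @param ts An [emm_series()] with at least 4 present (non-gap) values.
#' @param grid Ordered numeric vector of uniform monthly decimal-year times.
#' @return An [emm_series()] on the (possibly trimmed) grid.
#' @export
regularize_to_grid <- function(ts, grid) {
  assert_series(ts)
  ok <- !is.na(ts$values)
  if (sum(ok) < 4L) {
    stop("need at least 4 present values for spline regularization", call. = FALSE)
  }
  tt <- ts$times[ok]; vv <- ts$values[ok]
  lo <- min(tt); hi <- max(tt)
  inside <- grid >= lo - 1e-9 & grid <= hi + 1e-9
  if (!all(inside)) {
    warning(sprintf("grid trimmed to data support [%.4f, %.4f]: dropped %d points",
                    lo, hi, sum(!inside)), call. = FALSE)
    grid <- grid[inside]
  }
  if (length(grid) == 0L) stop("grid does not overlap data support", call. = FALSE)
  out <- stats::spline(tt, vv, xout = grid, method = "natural")$y
  emm_series(grid, out, name = ts$name, units = ts$units)
}

#' Standardize a series to mean 0, sample standard deviation 1
#'
#' The scaling used for cross-series comparison plots and as the default
#' input to cross mapping.
#'
#' @param ts An [emm_series()] with at least two distinct values.
#' @return A standardized [emm_series()].
#' @export
standardize <- function(ts) {
  assert_series(ts)
  v <- ts$values
  s <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize a constant series (zero variance)", call. = FALSE)
  }
  emm_series(ts$times, (v - mean(v, na.rm = TRUE)) / s, name = ts$name,
             units = NULL)
}

#' Lag-1 autocorrelation
#'
#' Sample product-moment correlation between the series and itself shifted by
#' one sample. Monthly environmental records of the kind this package targets
#' typically show values around 0.7-0.9, which is why cross mapping uses a
#' temporal exclusion radius (see [embedding_config()]).
#'
#' @param ts A regularized, nonconstant [emm_series()] of length >= 3.
#' @return A number in \[-1, 1\].
#' @export
lag1_autocorrelation <- function(ts) {
  assert_series(ts)
  v <- ts$values
  if (anyNA(v)) stop("series has gaps; regularize first", call. = FALSE)
  n <- length(v)
  if (n < 3L) stop("need length >= 3", call. = FALSE)
  if (stats::sd(v) == 0) stop("constant series", call. = FALSE)
  stats::cor(v[-n], v[-1])
}

#' Zero-lag linear cross correlation of two series
#'
#' Used as the linear reference line against which CCM skill curves are
#' compared.
#'
#' @param x,y Equal-length regularized [emm_series()].
#' @return A number in \[-1, 1\].
#' @export
linear_cross_correlation <- function(x, y) {
  assert_series(x); assert_series(y)
  if (length(x$times) != length(y$times)) {
    stop("series length mismatch", call. = FALSE)
  }
  stats::cor(x$values, y$values, use = "complete.obs")
}
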