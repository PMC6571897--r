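#' Construct a validated daily weather series
#'
#' The daily weather series is the sole climate input of the package: a
#' date-ordered table of daily minimum, maximum and mean air temperature
#' (degrees C) plus precipitation (mm). All bioclimatic index functions and
#' the analysis pipeline consume this object.
#'
#' @param records A data frame with columns `date` (Date), `tmin`, `tmax`,
#'   `precip` and optionally `tmean`. When `tmean` is absent it is
#'   reconstructed as `(tmin + tmax) / 2` and the series is flagged as
#'   having an imputed mean (see [weather_provenance()]).
#' @param station_id Character scalar identifying the station.
#'
#' @return A tibble of class `daily_weather` with columns `date`, `tmin`,
#'   `tmax`, `tmean`, `precip`, ordered by date, carrying attributes
#'   `station_id` and `tmean_imputed`.
#'
#' @details Invariants enforced: dates strictly increasing with no
#' duplicates; `tmin <= tmean <= tmax` on every day (a small tolerance of
#' 1e-6 degrees C absorbs rounding in input files); `precip >= 0`.
#' Violations raise errors naming the offending dates.
#'
#' @examples
#' d <- seq(as.Date("2010-06-01"), as.Date("2010-06-30"), by = "day")
#' s <- daily_weather_series(
#'   data.frame(date = d, tmin = 14, tmax = 28, precip = 0),
#'   station_id = "demo"
#' )
#' head(s)
#' @export
daily_weather_series <- function(records, station_id = "unknown") {
  records <- as.data.frame(records)
  required <- c("date", "tmin", "tmax", "precip")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("weather records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!inherits(records$date, "Date")) {
    records$date <- as.Date(records$date)
  }
  if (anyNA(records$date)) {
    stop("unparseable dates at row(s): ",
         paste(which(is.na(records$date)), collapse = ", "), call. = FALSE)
  }
  dup <- records$date[duplicated(records$date)]
  if (length(dup) > 0) {
    stop("duplicated date(s) in weather series: ",
         paste(unique(format(dup)), collapse = ", "), call. = FALSE)
  }
  records <- records[order(records$date), , drop = FALSE]

  tmean_imputed <- FALSE
  if (is.null(records$tmean)) {
    records$tmean <- (records$tmin + records$tmax) / 2
    tmean_imputed <- TRUE
  }

  tol <- 1e-6
  bad_order <- which(records$tmin > records$tmax + tol |
                       records$tmean > records$tmax + tol |
                       records$tmin > records$tmean + tol)
  if (length(bad_order) > 0) {
    stop("temperature ordering tmin <= tmean <= tmax violated on: ",
         paste(format(records$date[utils::head(bad_order, 10)]),
               collapse = ", "), call. = FALSE)
  }
  bad_p <- which(records$precip < 0)
  if (length(bad_p) > 0) {
    stop("negative precipitation on: ",
         paste(format(records$date[utils::head(bad_p, 10)]),
               collapse = ", "), call. = FALSE)
  }

  out <- tibble::as_tibble(
    records[, c("date", "tmin", "tmax", "tmean", "precip")]
  )
  attr(out, "station_id") <- station_id
  attr(out, "tmean_imputed") <- tmean_imputed
  class(out) <- c("daily_weather", class(out))
  out
}

#' Read daily weather records from a delimited text file
#'
#' @param path Path to a CSV file with one row per day.
#' @param col_map Named character vector mapping canonical names
#'   (`date`, `tmin`, `tmax`, `tmean`, `precip`) to the column names used in
#'   the file. Entries for columns already canonically named may be omitted;
#'   `tmean` is optional in the file.
#' @param date_format Either `"ymd"` (ISO-8601, default) or `"dmy"`
#'   (dd/mm/yyyy).
#' @param station_id Station identifier recorded on the series; defaults to
#'   the file name without extension.
#'
#' @return A `daily_weather` series (see [daily_weather_series()]).
#' @export
read_weather_csv <- function(path,
                             col_map = NULL,
                             date_format = c("ymd", "dmy"),
                             station_id = NULL) {
  date_format <- match.arg(date_format)
  if (!file.exists(path)) {
    stop("weather file not found: ", path, call. = FALSE)
  }
  if (is.null(station_id)) {
    station_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  canonical <- c("date", "tmin", "tmax", "tmean", "precip")
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad) > 0) {
      stop("unknown canonical name(s) in col_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) {
        stop("column '", src, "' (mapped to '", canon,
             "') not present in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("date", "tmin", "tmax", "precip")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("weather file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  fmt <- if (date_format == "ymd") "%Y-%m-%d" else "%d/%m/%Y"
  dates <- as.Date(as.character(raw$date), format = fmt)
  if (anyNA(dates)) {
    bad_rows <- which(is.na(dates))
    stop("unparseable date(s) in ", path, " at data row(s): ",
         paste(utils::head(bad_rows, 10), collapse = ", "),
         " (expected format ", date_format, ")", call. = FALSE)
  }
  raw$date <- dates
  daily_weather_series(raw, station_id = station_id)
}

#' Provenance metadata of a weather series
#'
#' @param series A `daily_weather` series.
#' @return A list with the station id, per-year completeness (fraction of
#'   calendar days present), whether `tmean` was reconstructed as the
#'   min/max midpoint, and the date range covered.
#' @export
weather_provenance <- function(series) {
  stopifnot(inherits(series, "daily_weather"))
  list(
    station_id = attr(series, "station_id"),
    tmean_imputed = isTRUE(attr(series, "tmean_imputed")),
    date_range = range(series$date),
    completeness = completeness_by_year(series)
  )
}

#' Per-year completeness of a daily series
#'
#' @param series A `daily_weather` series.
#' @return A tibble with columns `year`, `n_days`, `completeness` where
#'   completeness is the fraction of calendar days of that year present.
#' @export
completeness_by_year <- function(series) {
  yr <- as.integer(format(series$date, "%Y"))
  tab <- table(yr)
  years <- as.integer(names(tab))
  n_in_year <- ifelse(is_leap_year(years), 366L, 365L)
  tibble::tibble(
    year = years,
    n_days = as.integer(tab),
    completeness = as.integer(tab) / n_in_year
  )
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

#' Day-of-year (Julian day) of a calendar date
#'
#' Harvest dates are conventionally compared across years as 1-based
#' day-of-year ordinals (Jan 1 -> 1); leap years follow the true calendar,
#' so Dec 31 is 365 or 366.
#'
#' @param date A Date vector (or something coercible to Date).
#' @return Integer day-of-year.
#' @examples
#' julian_day(as.Date("2013-09-21")) # 264
#' @export
julian_day <- function(date) {
  date <- tryCatch(as.Date(date), error = function(e) as.Date(NA))
  if (anyNA(date)) stop("invalid calendar date", call. = FALSE)
  as.integer(format(date, "%j"))
}

# Season windows used throughout: closed [start, end] month-day intervals.
# growing_season and off_season follow the hydrological-season convention
# (May-Oct / Nov-Apr, northern hemisphere); winkler and huglin windows are
# the classical index accumulation periods.
.season_windows <- list(
  growing_season = list(start = c(5L, 1L),  end = c(10L, 31L)),
  off_season     = list(start = c(11L, 1L), end = c(4L, 30L)),
  winkler_window = list(start = c(4L, 1L),  end = c(10L, 31L)),
  huglin_window  = list(start = c(4L, 1L),  end = c(9L, 30L))
)

#' Season window definitions
#'
#' @param label One of `"growing_season"` (May 1-Oct 31),
#'   `"off_season"` (Nov 1-Apr 30), `"winkler_window"` (Apr 1-Oct 31),
#'   `"huglin_window"` (Apr 1-Sep 30).
#' @return A list with `label`, `start` and `end` as `c(month, day)`
#'   integer pairs; windows are closed intervals.
#' @export
season_window <- function(label = c("growing_season", "off_season",
                                    "winkler_window", "huglin_window")) {
  label <- match.arg(label)
  c(list(label = label), .season_windows[[label]])
}

# Dates of a within-year closed window [start_md, end_md] for `year`.
window_dates <- function(year, start_md, end_md) {
  seq(as.Date(sprintf("%04d-%02d-%02d", year, start_md[1], start_md[2])),
      as.Date(sprintf("%04d-%02d-%02d", year, end_md[1], end_md[2])),
      by = "day")
}

# Subset of `series` falling inside a within-year window; errors if the
# fraction of window days present is below `min_coverage`.
window_slice <- function(series, year, start_md, end_md,
                         min_coverage = 0.9, what = "window") {
  dates <- window_dates(year, start_md, end_md)
  sl <- series[series$date %in% dates, , drop = FALSE]
  frac <- nrow(sl) / length(dates)
  if (frac < min_coverage) {
    stop(sprintf(
      "insufficient coverage for %s of %d: %.1f%% of days present (need %.0f%%)",
      what, year, 100 * frac, 100 * min_coverage), call. = FALSE)
  }
  sl
}

#' Aggregate a daily series to monthly climate summaries
#'
#' @param series A `daily_weather` series.
#' @return A tibble with one row per (year, month) having at least one day:
#'   `year`, `month`, `mean_t` (arithmetic mean of daily mean temperature,
#'   degrees C), `total_p` (sum of daily precipitation, mm), `n_days`.
#' @export
aggregate_monthly <- function(series) {
  stopifnot(inherits(series, "daily_weather"))
  if (nrow(series) == 0) stop("empty weather series", call. = FALSE)
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  df <- data.frame(year = yr, month = mo,
                   tmean = series$tmean, precip = series$precip)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$year, .data$month),
    mean_t = mean(.data$tmean),
    total_p = sum(.data$precip),
    n_days = dplyr::n(),
    .groups = "drop"
  )
  tibble::as_tibble(out[order(out$year, out$month), ])
}

#' Split vintage-year precipitation into hydrological seasons
#'
#' Precipitation attributed to a vintage is split between the growing
#' season (May-Oct of the vintage year) and the off-season "hydrological
#' winter" (Nov of the previous calendar year through Apr of the vintage
#' year), which recharges soil water before the season.
#'
#' @param series A `daily_weather` series.
#' @param year Vintage year.
#' @param min_coverage Minimum fraction of the Nov-Oct window that must be
#'   present (default 0.9); below it the computation refuses rather than
#'   extrapolating.
#' @return A list with `growing_p` (mm), `off_p` (mm) and `off_fraction`
#'   = `off_p / (growing_p + off_p)`.
#' @export
split_hydrological <- function(series, year, min_coverage = 0.9) {
  stopifnot(inherits(series, "daily_weather"))
  off_dates <- seq(as.Date(sprintf("%04d-11-01", year - 1)),
                   as.Date(sprintf("%04d-04-30", year)), by = "day")
  grow_dates <- window_dates(year, c(5L, 1L), c(10L, 31L))
  all_dates <- c(off_dates, grow_dates)
  present <- series$date %in% all_dates
  frac <- sum(present) / length(all_dates)
  if (frac < min_coverage) {
    stop(sprintf(
      "insufficient coverage for hydrological year %d: %.1f%% of days present (need %.0f%%)",
      year, 100 * frac, 100 * min_coverage), call. = FALSE)
  }
  off_p <- sum(series$precip[series$date %in% off_dates])
  growing_p <- sum(series$precip[series$date %in% grow_dates])
  total <- growing_p + off_p
  list(
    growing_p = growing_p,
    off_p = off_p,
    off_fraction = if (total > 0) off_p / total else NA_real_
  )
}

#' Count rainy days in a calendar year
#'
#' A rainy day has precipitation strictly greater than the threshold
#' (default 1 mm; the strict inequality is the recorded convention).
#'
#' @param series A `daily_weather` series.
#' @param year Calendar year.
#' @param threshold_mm Rain threshold in mm (default 1).
#' @return Integer count of days with `precip > threshold_mm`.
#' @export
rainy_days <- function(series, year, threshold_mm = 1) {
  stopifnot(inherits(series, "daily_weather"))
  yr <- as.integer(format(series$date, "%Y"))
  if (!year %in% yr) {
    stop("year ", year, " not present in series", call. = FALSE)
  }
  sum(series$precip[yr == year] > threshold_mm)
}

#' @export
print.daily_weather <- function(x, ...) {
  cat(sprintf("<daily_weather> station '%s': %d days, %s to %s%s\n",
              attr(x, "station_id"), nrow(x),
              format(min(x$date)), format(max(x$date)),
              if (isTRUE(attr(x, "tmean_imputed")))
                " (tmean imputed as (tmin+tmax)/2)" else ""))
  NextMethod()
  invisible(x)
}
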