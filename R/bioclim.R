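#' Winkler index (growing degree-days, Apr 1 - Oct 31)
#'
#' Degree-day accumulation of daily mean temperature above a 10 degrees C
#' base over the classical Winkler window. Negative daily contributions
#' are clipped at zero by default (the Winkler convention); set
#' `clip_negative = FALSE` to accumulate the raw excess.
#'
#' @param series A `daily_weather` series.
#' @param year Vintage (calendar) year.
#' @param clip_negative Clip daily `tmean - 10` at zero (default `TRUE`).
#' @param min_coverage Minimum fraction of the window that must be present.
#' @return Growing degree-days (degrees C x days).
#' @examples
#' s <- constant_weather_year(2011, tmean = 20)
#' winkler_index(s, 2011) # (20 - 10) * 214 = 2140
#' @export
winkler_index <- function(series, year, clip_negative = TRUE,
                          min_coverage = 0.9) {
  sl <- window_slice(series, year, c(4L, 1L), c(10L, 31L),
                     min_coverage, "Winkler window (Apr-Oct)")
  dd <- sl$tmean - 10
  if (clip_negative) dd <- pmax(0, dd)
  sum(dd)
}

#' Huglin heliothermal index (Apr 1 - Sep 30)
#'
#' `d * sum(max(0, ((tmean - 10) + (tmax - 10)) / 2))` over April-September,
#' where `d` is the latitude-dependent day-length coefficient (1.03 in
#' mid-latitude grape-growing areas such as central Italy).
#'
#' @inheritParams winkler_index
#' @param d Day-length coefficient, in \[1.00, 1.06\].
#' @return Growing degree-days (degrees C x days).
#' @export
huglin_index <- function(series, year, d = 1.03, clip_negative = TRUE,
                         min_coverage = 0.9) {
  if (!is.numeric(d) || length(d) != 1 || d < 1.00 || d > 1.06) {
    stop("day-length coefficient d must lie in [1.00, 1.06]", call. = FALSE)
  }
  sl <- window_slice(series, year, c(4L, 1L), c(9L, 30L),
                     min_coverage, "Huglin window (Apr-Sep)")
  dd <- ((sl$tmean - 10) + (sl$tmax - 10)) / 2
  if (clip_negative) dd <- pmax(0, dd)
  d * sum(dd)
}

#' Cool night index (mean September minimum temperature)
#'
#' @inheritParams winkler_index
#' @return Mean of daily `tmin` over September, degrees C; a proxy for
#'   night coolness during ripening.
#' @export
cool_night_index <- function(series, year, min_coverage = 0.9) {
  sl <- window_slice(series, year, c(9L, 1L), c(9L, 30L),
                     min_coverage, "September")
  mean(sl$tmin)
}

#' Growing-season average temperature (Apr 1 - Oct 31)
#'
#' @inheritParams winkler_index
#' @return Mean of daily `tmean` over the growing window, degrees C.
#' @export
gst <- function(series, year, min_coverage = 0.9) {
  sl <- window_slice(series, year, c(4L, 1L), c(10L, 31L),
                     min_coverage, "GST window (Apr-Oct)")
  mean(sl$tmean)
}

#' Length of the growing season
#'
#' Number of days in the calendar year with daily mean temperature
#' strictly above 10 degrees C.
#'
#' @inheritParams winkler_index
#' @return Integer count of days.
#' @export
lgs <- function(series, year, min_coverage = 0.9) {
  sl <- window_slice(series, year, c(1L, 1L), c(12L, 31L),
                     min_coverage, "calendar year")
  sum(sl$tmean > 10)
}

#' Count days crossing a temperature threshold within a season window
#'
#' Implements the threshold-day indices: frost days (`tmin <= 0`), ice days
#' (`tmax <= 0`), moderate hot days (`tmax >= 25`) and extreme warm events
#' (`tmax >= 30`). Comparisons are inclusive, as conventionally printed.
#'
#' @inheritParams winkler_index
#' @param window A season window from [season_window()], or a list with
#'   `start`/`end` month-day pairs. Defaults to the full calendar year.
#' @param variable `"tmin"` or `"tmax"`.
#' @param op `">="` or `"<="`.
#' @param threshold Threshold temperature, degrees C.
#' @return Integer count of days satisfying the comparison.
#' @export
threshold_days <- function(series, year, window = NULL,
                           variable = c("tmax", "tmin"),
                           op = c(">=", "<="),
                           threshold = 30,
                           min_coverage = 0.9) {
  variable <- match.arg(variable)
  op <- match.arg(op)
  if (is.null(window)) {
    start_md <- c(1L, 1L); end_md <- c(12L, 31L); lab <- "calendar year"
  } else {
    start_md <- window$start; end_md <- window$end
    lab <- if (!is.null(window$label)) window$label else "window"
  }
  sl <- window_slice(series, year, start_md, end_md, min_coverage, lab)
  v <- sl[[variable]]
  if (op == ">=") sum(v >= threshold) else sum(v <= threshold)
}

#' Selyaninov hydrothermic coefficient (HTC)
#'
#' `10 * P / DD` where `P` is total precipitation and `DD` the degree-day
#' sum `max(0, tmean - 10)`, both over Apr 1 - Sep 30. By default the
#' numerator and denominator share the same Apr-Sep window (the internally
#' consistent Selyaninov formulation); `wi_window = "apr_oct"` instead
#' divides by the full Apr-Oct Winkler accumulation.
#'
#' @inheritParams winkler_index
#' @param wi_window `"apr_sep"` (default, aligned windows) or `"apr_oct"`.
#' @return Dimensionless moisture-availability coefficient (values around
#'   1 indicate adequate growing-season water supply; < 0.5 drought).
#' @export
htc <- function(series, year, wi_window = c("apr_sep", "apr_oct"),
                min_coverage = 0.9) {
  wi_window <- match.arg(wi_window)
  sl <- window_slice(series, year, c(4L, 1L), c(9L, 30L),
                     min_coverage, "HTC window (Apr-Sep)")
  p <- sum(sl$precip)
  dd <- if (wi_window == "apr_sep") {
    sum(pmax(0, sl$tmean - 10))
  } else {
    winkler_index(series, year, min_coverage = min_coverage)
  }
  if (dd <= 0) {
    stop("HTC undefined: degree-day sum is zero for ", year, call. = FALSE)
  }
  10 * p / dd
}

#' Maximum temperature in the month before harvest
#'
#' By default the trailing 30-day window ending the day before harvest
#' (continuous across varying harvest dates); `mode = "calendar"` uses the
#' full calendar month preceding the harvest month instead.
#'
#' @param series A `daily_weather` series.
#' @param harvest_date Harvest date (Date).
#' @param mode `"trailing"` (default) or `"calendar"`.
#' @param min_coverage Minimum fraction of the window that must be present.
#' @return Maximum `tmax` over the window, degrees C.
#' @export
max_temp_prior_to_harvest <- function(series, harvest_date,
                                      mode = c("trailing", "calendar"),
                                      min_coverage = 0.9) {
  mode <- match.arg(mode)
  harvest_date <- as.Date(harvest_date)
  if (mode == "trailing") {
    dates <- seq(harvest_date - 30, harvest_date - 1, by = "day")
  } else {
    first_of_month <- as.Date(format(harvest_date, "%Y-%m-01"))
    prev_end <- first_of_month - 1
    prev_start <- as.Date(format(prev_end, "%Y-%m-01"))
    dates <- seq(prev_start, prev_end, by = "day")
  }
  sl <- series[series$date %in% dates, , drop = FALSE]
  frac <- nrow(sl) / length(dates)
  if (frac < min_coverage) {
    stop(sprintf(
      "insufficient coverage in pre-harvest window: %.1f%% of days present",
      100 * frac), call. = FALSE)
  }
  max(sl$tmax)
}

#' Class boundary tables for climate classification
#'
#' A class boundary table is an ordered set of contiguous half-open
#' intervals `[lower, upper)` covering the real line, each carrying a class
#' label; boundary values belong to the upper class.
#'
#' @param scheme Name of the scheme (free text).
#' @param labels Character vector of class labels, ordered from coldest.
#' @param breaks Numeric vector of interior breakpoints,
#'   `length(labels) - 1`, strictly increasing.
#' @return A tibble of class `class_boundary_table` with columns `label`,
#'   `lower`, `upper`.
#' @export
class_boundary_table <- function(scheme, labels, breaks) {
  if (length(breaks) != length(labels) - 1) {
    stop("need exactly length(labels) - 1 breaks", call. = FALSE)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(
    label = labels,
    lower = c(-Inf, breaks),
    upper = c(breaks, Inf)
  )
  attr(out, "scheme") <- scheme
  class(out) <- c("class_boundary_table", class(out))
  out
}

#' Default classification tables
#'
#' `gst_maturity_table()` gives growing-season temperature maturity classes
#' (intermediate 15-17, warm 17-19 degrees C, extended to the full published
#' scale). `wi_region_table()`, `hi_class_table()` and `ci_class_table()`
#' carry the multicriteria-classification defaults from the viticultural
#' zoning literature; they are configuration data, replaceable by
#' user-supplied [class_boundary_table()]s.
#'
#' @return A `class_boundary_table`.
#' @export
gst_maturity_table <- function() {
  class_boundary_table(
    scheme = "gst_maturity",
    labels = c("too cool", "cool", "intermediate", "warm",
               "hot", "very hot", "too hot"),
    breaks = c(13, 15, 17, 19, 21, 24)
  )
}

#' @rdname gst_maturity_table
#' @export
wi_region_table <- function() {
  class_boundary_table(
    scheme = "winkler_region",
    labels = c("Region I", "Region II", "Region III",
               "Region IV", "Region V"),
    breaks = c(1389, 1667, 1944, 2222)
  )
}

#' @rdname gst_maturity_table
#' @export
hi_class_table <- function() {
  class_boundary_table(
    scheme = "huglin_class",
    labels = c("very cool", "cool", "temperate", "temperate warm",
               "warm", "very warm"),
    breaks = c(1500, 1800, 2100, 2400, 3000)
  )
}

#' @rdname gst_maturity_table
#' @export
ci_class_table <- function() {
  class_boundary_table(
    scheme = "cool_night_class",
    labels = c("very cool nights", "cool nights",
               "temperate nights", "warm nights"),
    breaks = c(12, 14, 18)
  )
}

#' Classify an index value against a class boundary table
#'
#' @param value Numeric vector of index values.
#' @param table A [class_boundary_table()].
#' @return Character vector of class labels; a boundary value falls in the
#'   upper class (intervals are half-open `[lower, upper)`).
#' @examples
#' classify(19.6, gst_maturity_table()) # "hot"
#' @export
classify <- function(value, table) {
  stopifnot(inherits(table, "class_boundary_table"))
  idx <- findInterval(value, c(table$lower[1], table$upper),
                      left.open = FALSE)
  # findInterval with breaks (-Inf, b1..bk, Inf): value == b_i lands in the
  # interval starting at b_i, i.e. the upper class, as required.
  table$label[pmin(pmax(idx, 1L), nrow(table))]
}

#' Ombrothermic (Bagnouls-Gaussen) climatological profile
#'
#' Averages monthly mean temperature and monthly precipitation totals over a
#' period of years and flags dry months by the Bagnouls-Gaussen criterion:
#' a month is dry when mean precipitation (mm) falls below twice the mean
#' temperature (degrees C). The resulting 12-month profile is the data
#' behind an ombrothermic diagram.
#'
#' @param monthlies Monthly summaries from [aggregate_monthly()].
#' @param period Optional integer vector of years to include (default: all
#'   years present).
#' @return A tibble with one row per calendar month: `month`, `mean_t`,
#'   `mean_p`, `dry`, `n_years`.
#' @export
ombrothermic_profile <- function(monthlies, period = NULL) {
  if (!is.null(period)) {
    monthlies <- monthlies[monthlies$year %in% period, , drop = FALSE]
  }
  if (nrow(monthlies) == 0) {
    stop("no monthly summaries in the requested period", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(monthlies, .data$month),
    mean_t = mean(.data$mean_t),
    mean_p = mean(.data$total_p),
    n_years = dplyr::n(),
    .groups = "drop"
  )
  out$dry <- out$mean_p < 2 * out$mean_t
  tibble::as_tibble(out[order(out$month),
                        c("month", "mean_t", "mean_p", "dry", "n_years")])
}

#' Compute the full bioclimatic index set for a vintage
#'
#' Assembles every index of the standard viticultural suite for one vintage
#' year. Indices whose accumulation window fails the coverage threshold are
#' returned as `NA` (absent), never as zero.
#'
#' @inheritParams winkler_index
#' @param d Huglin day-length coefficient.
#' @param harvest_date Optional harvest date for the pre-harvest maximum
#'   temperature index.
#' @param htc_wi_window Window convention for the HTC denominator, see
#'   [htc()].
#' @return A one-row tibble: `year`, `lgs` (days), `gst` (degrees C), `wi`,
#'   `hi` (degree-days), `ci` (degrees C), `frost_days`, `ice_days`,
#'   `hot25_days`, `hot30_days` (counts), `tmax_pre_harvest` (degrees C or
#'   `NA`), `htc` (dimensionless), plus annual `total_p` (mm) and
#'   `rainy_days`.
#' @export
compute_index_set <- function(series, year, d = 1.03, clip_negative = TRUE,
                              harvest_date = NULL,
                              htc_wi_window = c("apr_sep", "apr_oct"),
                              min_coverage = 0.9) {
  htc_wi_window <- match.arg(htc_wi_window)
  try_idx <- function(expr) {
    tryCatch(expr, error = function(e) NA_real_)
  }
  gw <- season_window("winkler_window")
  tibble::tibble(
    year = as.integer(year),
    lgs = try_idx(lgs(series, year, min_coverage)),
    gst = try_idx(gst(series, year, min_coverage)),
    wi = try_idx(winkler_index(series, year, clip_negative, min_coverage)),
    hi = try_idx(huglin_index(series, year, d, clip_negative, min_coverage)),
    ci = try_idx(cool_night_index(series, year, min_coverage)),
    frost_days = try_idx(threshold_days(series, year, NULL, "tmin", "<=",
                                        0, min_coverage)),
    ice_days = try_idx(threshold_days(series, year, NULL, "tmax", "<=",
                                      0, min_coverage)),
    hot25_days = try_idx(threshold_days(series, year, gw, "tmax", ">=",
                                        25, min_coverage)),
    hot30_days = try_idx(threshold_days(series, year, gw, "tmax", ">=",
                                        30, min_coverage)),
    tmax_pre_harvest = if (is.null(harvest_date)) NA_real_ else
      try_idx(max_temp_prior_to_harvest(series, harvest_date,
                                        min_coverage = min_coverage)),
    htc = try_idx(htc(series, year, htc_wi_window, min_coverage)),
    total_p = try_idx({
      sl <- window_slice(series, year, c(1L, 1L), c(12L, 31L),
                         min_coverage, "calendar year")
      sum(sl$precip)
    }),
    rainy_days = try_idx({
      window_slice(series, year, c(1L, 1L), c(12L, 31L),
                   min_coverage, "calendar year")
      as.numeric(rainy_days(series, year))
    })
  )
}
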