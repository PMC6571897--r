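#' Read a phenology/quality CSV
#'
#' Expects columns `variety`, `year`, `harvest_date` (ISO-8601), `tss`,
#' `ta`, `ph`; the harvest date is converted to a 1-based Julian day.
#' Records are validated against sanity bounds (harvest day within
#' 150-330, positive sugar and acidity, pH within 2.5-4.5).
#'
#' @param path Path to the CSV file.
#' @return A tibble: `variety`, `year`, `harvest_jd`, `harvest_date`,
#'   `tss`, `ta`, `ph`.
#' @export
read_pheno_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("variety", "year", "harvest_date", "tss", "ta", "ph")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("phenology file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  hd <- as.Date(as.character(raw$harvest_date))
  jd <- julian_day(hd)
  bad <- which(jd < 150 | jd > 330 | raw$tss <= 0 | raw$ta <= 0 |
                 raw$ph < 2.5 | raw$ph > 4.5)
  if (length(bad) > 0) {
    stop("phenology records out of sanity bounds at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    variety = as.character(raw$variety),
    year = as.integer(raw$year),
    harvest_jd = jd,
    harvest_date = hd,
    tss = raw$tss, ta = raw$ta, ph = raw$ph
  )
}

#' Read an annual treatments CSV
#'
#' Expects columns `year`, `downy`, `powdery` (counts of treatments
#' against downy and powdery mildew).
#'
#' @param path Path to the CSV file.
#' @return A tibble: `year`, `downy_mildew_n`, `powdery_mildew_n`,
#'   `total_n`.
#' @export
read_treatments_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("year", "downy", "powdery")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("treatments file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(raw$downy < 0 | raw$powdery < 0)) {
    stop("treatment counts must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    year = as.integer(raw$year),
    downy_mildew_n = as.integer(raw$downy),
    powdery_mildew_n = as.integer(raw$powdery),
    total_n = as.integer(raw$downy + raw$powdery)
  )
}

#' Assemble and validate an analysis configuration
#'
#' @param sub_areas Named list; each element is a list with `weather`
#'   (path to the station CSV) and `years` (integer vector of vintages to
#'   analyse).
#' @param pheno Path to the phenology/quality CSV.
#' @param treatments Optional path to the treatments CSV.
#' @param variety_map Named character vector mapping each variety code to
#'   exactly one sub-area name.
#' @param alpha Significance level for correlation screens.
#' @param d Huglin day-length coefficient.
#' @param clip_negative Degree-day clipping convention (see
#'   [winkler_index()]).
#' @param htc_wi_window HTC denominator window (see [htc()]).
#' @param min_coverage Completeness threshold for windowed computations.
#' @param split_year Optional year starting the second period of the
#'   decade comparison; defaults to the midpoint of each sub-area's range.
#' @param n_components Components retained in the per-group PCA.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(sub_areas, pheno, treatments = NULL,
                            variety_map, alpha = 0.05, d = 1.03,
                            clip_negative = TRUE,
                            htc_wi_window = "apr_sep",
                            min_coverage = 0.9,
                            split_year = NULL,
                            n_components = 3) {
  if (is.null(names(sub_areas)) || any(names(sub_areas) == "")) {
    stop("sub_areas must be a named list", call. = FALSE)
  }
  for (nm in names(sub_areas)) {
    sa <- sub_areas[[nm]]
    if (is.null(sa$weather) || is.null(sa$years) || length(sa$years) == 0) {
      stop("sub-area '", nm, "' needs a weather path and a non-empty ",
           "year range", call. = FALSE)
    }
  }
  if (is.null(names(variety_map)) ||
      !all(variety_map %in% names(sub_areas))) {
    stop("every variety must map to exactly one declared sub-area",
         call. = FALSE)
  }
  structure(
    list(sub_areas = sub_areas, pheno = pheno, treatments = treatments,
         variety_map = variety_map, alpha = alpha, d = d,
         clip_negative = clip_negative, htc_wi_window = htc_wi_window,
         min_coverage = min_coverage, split_year = split_year,
         n_components = n_components),
    class = "analysis_config"
  )
}

#' Compare mean temperature between two sub-periods
#'
#' Averages annual mean temperatures (complete years only, per the series
#' completeness threshold) within the periods before and from
#' `split_year`, and reports the warming step between them.
#'
#' @param series A `daily_weather` series.
#' @param split_year First year of the second period.
#' @param min_coverage Completeness threshold for a year to count.
#' @return A list: `first_period_mean`, `second_period_mean`,
#'   `difference` (second minus first, degrees C).
#' @export
decade_comparison <- function(series, split_year, min_coverage = 0.9) {
  stopifnot(inherits(series, "daily_weather"))
  comp <- completeness_by_year(series)
  years <- comp$year[comp$completeness >= min_coverage]
  if (!any(years < split_year) || !any(years >= split_year)) {
    stop("split_year ", split_year,
         " leaves an empty period in ", paste(range(comp$year),
                                              collapse = "-"),
         call. = FALSE)
  }
  yr <- as.integer(format(series$date, "%Y"))
  annual <- vapply(years, function(y) mean(series$tmean[yr == y]),
                   numeric(1))
  first <- mean(annual[years < split_year])
  second <- mean(annual[years >= split_year])
  list(first_period_mean = first, second_period_mean = second,
       difference = second - first)
}

# Annual index table for one sub-area, with growing-season precipitation
# appended where the hydrological window is covered.
sub_area_indices <- function(series, years, config) {
  idx <- dplyr::bind_rows(lapply(years, function(y) {
    compute_index_set(series, y, d = config$d,
                      clip_negative = config$clip_negative,
                      htc_wi_window = config$htc_wi_window,
                      min_coverage = config$min_coverage)
  }))
  idx$growing_p <- vapply(years, function(y) {
    tryCatch(split_hydrological(series, y, config$min_coverage)$growing_p,
             error = function(e) NA_real_)
  }, numeric(1))
  idx$off_p <- vapply(years, function(y) {
    tryCatch(split_hydrological(series, y, config$min_coverage)$off_p,
             error = function(e) NA_real_)
  }, numeric(1))
  idx
}

#' Run the full climate-phenology analysis
#'
#' Executes the end-to-end pipeline per sub-area: weather validation,
#' monthly aggregation, the annual bioclimatic index suite, growing-season
#' temperature classification, ombrothermic profile, sub-period
#' temperature comparison, per-variety ripening/quality trends and
#' correlation screens, a group-wise standardised PCA of climate and
#' quality variables, and (when treatment counts are supplied) an
#' exponential treatment-growth fit. Varieties are never mixed across
#' sub-areas: each variety's statistics use only its own station's
#' indices.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory; when given, all tables are
#'   written as CSV plus a JSON provenance sidecar.
#' @return A `run_report` list with elements `indices`, `classification`,
#'   `monthly`, `ombrothermic`, `decades`, `variety_reports`, `pca`,
#'   `treatment_fit`, `provenance`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))

  pheno <- read_pheno_csv(config$pheno)
  unmapped <- setdiff(unique(pheno$variety), names(config$variety_map))
  if (length(unmapped) > 0) {
    stop("variety(ies) not mapped to a sub-area: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  report <- list(indices = list(), classification = list(),
                 monthly = list(), ombrothermic = list(), decades = list(),
                 variety_reports = list(), pca = list(),
                 treatment_fit = NULL)
  gst_table <- gst_maturity_table()

  for (nm in names(config$sub_areas)) {
    sa <- config$sub_areas[[nm]]
    series <- read_weather_csv(sa$weather)
    years <- as.integer(sa$years)

    idx <- sub_area_indices(series, years, config)
    report$indices[[nm]] <- idx
    report$classification[[nm]] <- tibble::tibble(
      year = idx$year,
      gst = idx$gst,
      gst_class = ifelse(is.na(idx$gst), NA_character_,
                         classify(idx$gst, gst_table))
    )
    monthly <- aggregate_monthly(series)
    report$monthly[[nm]] <- monthly
    report$ombrothermic[[nm]] <- ombrothermic_profile(
      monthly, period = years)

    split_year <- config$split_year
    if (is.null(split_year)) {
      split_year <- floor(stats::median(years)) + 1L
    }
    report$decades[[nm]] <- tryCatch(
      decade_comparison(series, split_year, config$min_coverage),
      error = function(e) NULL)

    sa_varieties <- names(config$variety_map)[config$variety_map == nm]
    sub_pheno <- pheno[pheno$variety %in% sa_varieties, , drop = FALSE]
    if (nrow(sub_pheno) > 0) {
      report$variety_reports[[nm]] <- variety_climate_report(
        sub_pheno, idx, alpha = config$alpha)
      joined <- report$variety_reports[[nm]]$joined
      pca_vars <- intersect(
        c("harvest_jd", "tss", "ta", "ph", "wi", "hi", "gst", "ci",
          "hot30_days", "total_p"),
        names(joined))
      tab <- joined[, pca_vars, drop = FALSE]
      tab <- tab[stats::complete.cases(tab), , drop = FALSE]
      if (nrow(tab) >= 3) {
        report$pca[[nm]] <- run_pca(tab,
                                    n_components = config$n_components)
      }
    }
  }

  if (!is.null(config$treatments)) {
    tr <- read_treatments_csv(config$treatments)
    pos <- tr$total_n > 0
    report$treatment_fit <- exponential_trend(tr$year[pos],
                                              tr$total_n[pos])
    report$treatments <- tr
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("vitibioclim")),
    config = unclass(config),
    generated = "run_full_analysis"
  )
  class(report) <- "run_report"

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  invisible(report)
}

# Write every table of a run report as CSV plus a JSON provenance sidecar.
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$indices)) {
    readr::write_csv(report$indices[[nm]],
                     file.path(out_dir, paste0(nm, "_indices.csv")))
    readr::write_csv(report$classification[[nm]],
                     file.path(out_dir, paste0(nm, "_classification.csv")))
    readr::write_csv(report$monthly[[nm]],
                     file.path(out_dir, paste0(nm, "_monthly.csv")))
    readr::write_csv(report$ombrothermic[[nm]],
                     file.path(out_dir, paste0(nm, "_ombrothermic.csv")))
    vr <- report$variety_reports[[nm]]
    if (!is.null(vr)) {
      readr::write_csv(vr$trends,
                       file.path(out_dir, paste0(nm, "_trends.csv")))
      for (v in names(vr$correlations)) {
        cm <- vr$correlations[[v]]
        readr::write_csv(
          tibble::as_tibble(cm$r, rownames = "variable"),
          file.path(out_dir, paste0(nm, "_cor_", v, ".csv")))
        readr::write_csv(
          tibble::as_tibble(cm$significant, rownames = "variable"),
          file.path(out_dir, paste0(nm, "_cor_", v, "_significant.csv")))
      }
    }
    pc <- report$pca[[nm]]
    if (!is.null(pc)) {
      readr::write_csv(
        tibble::as_tibble(pc$loadings, rownames = "variable"),
        file.path(out_dir, paste0(nm, "_pca_loadings.csv")))
      readr::write_csv(
        tibble::as_tibble(pc$scores),
        file.path(out_dir, paste0(nm, "_pca_scores.csv")))
      readr::write_csv(
        tibble::tibble(component = seq_along(pc$explained_variance),
                       explained = pc$explained_variance,
                       cumulative = pc$cumulative_variance),
        file.path(out_dir, paste0(nm, "_pca_variance.csv")))
    }
  }
  if (!is.null(report$treatment_fit)) {
    tf <- report$treatment_fit
    readr::write_csv(
      tibble::tibble(model = tf$model, growth_rate = tf$slope,
                     intercept = tf$intercept, r2 = tf$r2,
                     p_value = tf$p_value, n = tf$n),
      file.path(out_dir, "treatment_fit.csv"))
  }
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(out_dir)
}
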