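#' Constant-climate synthetic year
#'
#' A full calendar year of identical days: the degenerate input for which
#' every bioclimatic index has a closed form. Useful in examples and
#' exactness checks.
#'
#' @param year Calendar year.
#' @param tmean Daily mean temperature, degrees C.
#' @param tmin,tmax Daily minimum/maximum; default symmetric 5 degrees C
#'   around `tmean`.
#' @param precip Daily precipitation, mm.
#' @return A `daily_weather` series covering the whole year.
#' @examples
#' s <- constant_weather_year(2011, tmean = 20)
#' winkler_index(s, 2011) # (20 - 10) * 214
#' @export
constant_weather_year <- function(year, tmean = 15, tmin = tmean - 5,
                                  tmax = tmean + 5, precip = 0) {
  d <- seq(as.Date(sprintf("%04d-01-01", year)),
           as.Date(sprintf("%04d-12-31", year)), by = "day")
  daily_weather_series(
    data.frame(date = d, tmin = tmin, tmax = tmax, tmean = tmean,
               precip = precip),
    station_id = "constant"
  )
}

#' Configuration for the stochastic daily weather generator
#'
#' The generator emulates a Mediterranean dry-summer (Koeppen Csa) regime:
#' a sinusoidal seasonal temperature cycle around a warming secular trend
#' with AR(1) day-to-day noise, a fixed diurnal range, and Bernoulli-gamma
#' daily precipitation with month-specific wet probabilities and amounts.
#' Defaults are calibrated to an annual mean near 13.5 degrees C warming at
#' 0.08 degrees C/yr, ~1000 mm/yr precipitation concentrated in autumn and
#' spring with 35-40% falling in the Nov-Apr off-season, and a restricted
#' Jun-Aug dryness period.
#'
#' @param base_mean_t Annual mean temperature (degrees C) in the first
#'   simulated year.
#' @param seasonal_amplitude Amplitude of the seasonal sine cycle
#'   (degrees C); the cycle is centred within each year so the noise-free
#'   annual mean equals `base_mean_t` plus the trend exactly.
#' @param warming_rate Linear warming trend, degrees C per year.
#' @param ar1_coeff AR(1) autocorrelation of daily temperature noise, in
#'   \[0, 1); the default 0.7 produces realistic multi-day heat spells.
#' @param noise_sd Stationary standard deviation of the AR(1) noise
#'   (degrees C).
#' @param diurnal_range Fixed Tmax - Tmin spread (degrees C); Tmax/Tmin
#'   sit half a range above/below Tmean.
#' @param peak_doy Day-of-year at which the seasonal cycle peaks
#'   (default 205, late July).
#' @param wet_prob_by_month 12 probabilities of a wet day.
#' @param gamma_shape Shape of the gamma wet-day amount distribution.
#' @param gamma_scale_by_month 12 gamma scales (mm); the default is derived
#'   from `monthly_precip_mm` so that expected monthly totals match the
#'   calibration targets.
#' @param monthly_precip_mm 12 target expected monthly precipitation totals
#'   (mm) used to derive the default gamma scales.
#' @param years Integer vector of calendar years to simulate.
#' @param seed Integer RNG seed; the simulation is a pure function of the
#'   configuration including the seed.
#' @return A validated list of class `weather_sim_config`.
#' @export
weather_sim_config <- function(base_mean_t = 13.5,
                               seasonal_amplitude = 9,
                               warming_rate = 0.08,
                               ar1_coeff = 0.7,
                               noise_sd = 2.2,
                               diurnal_range = 10,
                               peak_doy = 205,
                               wet_prob_by_month = c(0.30, 0.28, 0.30, 0.32,
                                                     0.30, 0.18, 0.10, 0.12,
                                                     0.30, 0.35, 0.34, 0.30),
                               gamma_shape = 0.9,
                               gamma_scale_by_month = NULL,
                               monthly_precip_mm = c(48, 45, 58, 72, 145, 38,
                                                     22, 28, 190, 200, 95, 62),
                               years = 1995:2015,
                               seed = 42) {
  if (!(ar1_coeff >= 0 && ar1_coeff < 1)) {
    stop("ar1_coeff must lie in [0, 1)", call. = FALSE)
  }
  if (length(wet_prob_by_month) != 12 ||
      any(wet_prob_by_month < 0 | wet_prob_by_month > 1)) {
    stop("wet_prob_by_month must be 12 probabilities in [0, 1]",
         call. = FALSE)
  }
  if (diurnal_range <= 0) stop("diurnal_range must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (gamma_shape <= 0) stop("gamma_shape must be > 0", call. = FALSE)
  if (length(years) < 1) stop("years must be non-empty", call. = FALSE)
  month_days <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  if (is.null(gamma_scale_by_month)) {
    if (length(monthly_precip_mm) != 12 || any(monthly_precip_mm < 0)) {
      stop("monthly_precip_mm must be 12 non-negative totals", call. = FALSE)
    }
    expected_wet_days <- month_days * wet_prob_by_month
    gamma_scale_by_month <- ifelse(
      expected_wet_days > 0,
      monthly_precip_mm / (expected_wet_days * gamma_shape),
      0
    )
  }
  if (length(gamma_scale_by_month) != 12 || any(gamma_scale_by_month < 0)) {
    stop("gamma_scale_by_month must be 12 non-negative scales",
         call. = FALSE)
  }
  structure(
    list(base_mean_t = base_mean_t,
         seasonal_amplitude = seasonal_amplitude,
         warming_rate = warming_rate,
         ar1_coeff = ar1_coeff,
         noise_sd = noise_sd,
         diurnal_range = diurnal_range,
         peak_doy = peak_doy,
         wet_prob_by_month = wet_prob_by_month,
         gamma_shape = gamma_shape,
         gamma_scale_by_month = gamma_scale_by_month,
         years = as.integer(years),
         seed = as.integer(seed)),
    class = "weather_sim_config"
  )
}

#' Simulate a daily weather series
#'
#' @param config A [weather_sim_config()].
#' @param station_id Station identifier stamped on the series.
#' @return A `daily_weather` series covering `config$years`.
#' @details The daily mean temperature is
#'   `base + amplitude * sin(2 pi (doy - phase) / 365.25) +
#'   warming_rate * (year - year0) + AR(1) noise`, with the seasonal term
#'   centred within each calendar year; `tmax = tmean + diurnal_range / 2`
#'   and `tmin = tmean - diurnal_range / 2`. Daily precipitation is a
#'   Bernoulli(wet probability of the month) indicator times a
#'   Gamma(shape, scale of the month) amount.
#' @export
simulate_weather <- function(config, station_id = "synthetic") {
  stopifnot(inherits(config, "weather_sim_config"))
  withr::with_seed(config$seed, {
    year0 <- min(config$years)
    all_dates <- seq(as.Date(sprintf("%04d-01-01", min(config$years))),
                     as.Date(sprintf("%04d-12-31", max(config$years))),
                     by = "day")
    yr <- as.integer(format(all_dates, "%Y"))
    keep <- yr %in% config$years
    all_dates <- all_dates[keep]; yr <- yr[keep]
    doy <- as.integer(format(all_dates, "%j"))
    mo <- as.integer(format(all_dates, "%m"))
    n <- length(all_dates)

    # phase so the sine peaks at peak_doy
    phase <- config$peak_doy - 365.25 / 4
    seas <- config$seasonal_amplitude * sin(2 * pi * (doy - phase) / 365.25)
    # centre the seasonal cycle within each year: its annual mean is 0
    seas <- seas - stats::ave(seas, yr)

    trend <- config$warming_rate * (yr - year0)

    eps <- numeric(n)
    if (config$noise_sd > 0) {
      # stationary AR(1): recursive filter of white innovations seeded
      # from the stationary marginal, so every day has sd = noise_sd
      innov_sd <- config$noise_sd * sqrt(1 - config$ar1_coeff^2)
      e0 <- stats::rnorm(1, 0, config$noise_sd)
      z <- stats::rnorm(n, 0, innov_sd)
      eps <- as.numeric(stats::filter(z, config$ar1_coeff,
                                      method = "recursive", init = e0))
    }

    tmean <- config$base_mean_t + seas + trend + eps
    half <- config$diurnal_range / 2

    wet <- stats::rbinom(n, 1, config$wet_prob_by_month[mo])
    amount <- stats::rgamma(n, shape = config$gamma_shape,
                            scale = pmax(config$gamma_scale_by_month[mo],
                                         1e-12))
    precip <- wet * amount

    daily_weather_series(
      data.frame(date = all_dates,
                 tmin = tmean - half,
                 tmax = tmean + half,
                 tmean = tmean,
                 precip = precip),
      station_id = station_id
    )
  })
}

#' Default genotype response profiles
#'
#' Synthetic per-variety parameters encoding the qualitative response
#' structure of the seven varieties tracked by the analysis: a thermal-time
#' (degree-day) target from April 1 to technological ripeness, harvest-date
#' plasticity, and linear berry-quality responses to the count of extreme
#' hot days (Tmax >= 30 degrees C) in the growing season. International
#' varieties get small plasticity (clear climate-driven harvest trends);
#' the autochthonous Grechetto (GR) and Aleatico (A) get large plasticity
#' and near-zero sugar response so their harvest dates fluctuate without
#' trend. Sugar responses are negative for Cabernet Sauvignon (CS) and
#' Sangiovese (S), positive for Cabernet Franc (CF) and Merlot (M);
#' titratable acidity responds negatively to hot days for every variety.
#' All coefficients are synthetic: they encode signs and plausible
#' magnitudes, not measured physiology.
#'
#' @return A tibble with columns `variety`, `group` (white/red), `origin`
#'   (international/autochthonous), `gdd_target` (degree-days),
#'   `plasticity_sd` (days), `tss_base` (degrees Brix), `tss_per_hot_day`,
#'   `tss_sd`, `ta_base` (g/L tartaric acid), `ta_per_hot_day`, `ta_sd`,
#'   `ph_base`, `ph_per_hot_day`, `ph_sd`.
#' @export
genotype_profiles <- function() {
  tibble::tribble(
    ~variety, ~group, ~origin, ~gdd_target, ~plasticity_sd,
    ~tss_base, ~tss_per_hot_day, ~tss_sd,
    ~ta_base, ~ta_per_hot_day, ~ta_sd,
    ~ph_base, ~ph_per_hot_day, ~ph_sd,
    "GR", "white", "autochthonous", 1420, 10.0,
    20.5,  0.00, 0.35, 7.5, -0.06, 0.35, 3.20, 0.008, 0.05,
    "CH", "white", "international", 1330, 2.5,
    21.0, -0.03, 0.35, 8.0, -0.08, 0.35, 3.15, 0.010, 0.05,
    "A",  "red",  "autochthonous", 1450, 9.0,
    20.0,  0.00, 0.35, 7.0, -0.06, 0.35, 3.30, 0.008, 0.05,
    "S",  "red",  "international", 1500, 3.0,
    21.5, -0.10, 0.35, 7.5, -0.08, 0.35, 3.25, 0.010, 0.05,
    "CS", "red",  "international", 1520, 3.0,
    22.0, -0.12, 0.35, 7.0, -0.08, 0.35, 3.35, 0.010, 0.05,
    "CF", "red",  "international", 1400, 3.0,
    21.5,  0.10, 0.35, 6.8, -0.08, 0.35, 3.40, 0.010, 0.05,
    "M",  "red",  "international", 1380, 3.0,
    22.0,  0.12, 0.35, 6.5, -0.08, 0.35, 3.45, 0.010, 0.05
  )
}

#' Simulate per-variety phenology and berry quality
#'
#' Harvest is reached on the first day on which growing degree-days
#' (base 10 degrees C) accumulated from April 1 meet the genotype's
#' thermal-time target, plus Gaussian day jitter (`plasticity_sd`). Berry
#' quality responds linearly to the number of growing-season days with
#' Tmax >= 30 degrees C: `tss = tss_base + tss_per_hot_day * hot30 + noise`
#' and likewise for titratable acidity (floored just above zero) and pH.
#'
#' @param weather A `daily_weather` series.
#' @param profiles A profile tibble as from [genotype_profiles()].
#' @param seed Integer RNG seed.
#' @param years Years to simulate (default: all complete years with full
#'   Apr 1 - Oct 31 coverage).
#' @return A tibble of phenology/quality records: `variety`, `year`,
#'   `harvest_jd`, `harvest_date`, `tss`, `ta`, `ph`, `hot30_days`. Years
#'   in which a genotype's target is not reached yield an `NA` record with
#'   a warning.
#' @export
simulate_phenology_quality <- function(weather, profiles, seed = 1,
                                       years = NULL) {
  stopifnot(inherits(weather, "daily_weather"))
  if (is.null(years)) {
    years <- completeness_by_year(weather)
    years <- years$year[years$completeness > 0.99]
  }
  withr::with_seed(seed, {
    rows <- list()
    for (y in years) {
      win <- window_slice(weather, y, c(4L, 1L), c(10L, 31L),
                          min_coverage = 0.99, "growing window")
      cum_gdd <- cumsum(pmax(0, win$tmean - 10))
      hot30 <- sum(win$tmax >= 30)
      for (i in seq_len(nrow(profiles))) {
        pr <- profiles[i, ]
        hit <- which(cum_gdd >= pr$gdd_target)
        if (length(hit) == 0) {
          warning("gdd_target ", pr$gdd_target, " for ", pr$variety,
                  " not reached in ", y, "; record marked absent",
                  call. = FALSE)
          rows[[length(rows) + 1]] <- tibble::tibble(
            variety = pr$variety, year = y, harvest_jd = NA_integer_,
            harvest_date = as.Date(NA), tss = NA_real_, ta = NA_real_,
            ph = NA_real_, hot30_days = hot30)
          next
        }
        base_date <- win$date[hit[1]]
        jitter <- round(stats::rnorm(1, 0, pr$plasticity_sd))
        hdate <- base_date + jitter
        rows[[length(rows) + 1]] <- tibble::tibble(
          variety = pr$variety,
          year = y,
          harvest_jd = julian_day(hdate),
          harvest_date = hdate,
          tss = pr$tss_base + pr$tss_per_hot_day * hot30 +
            stats::rnorm(1, 0, pr$tss_sd),
          ta = max(0.5, pr$ta_base + pr$ta_per_hot_day * hot30 +
                     stats::rnorm(1, 0, pr$ta_sd)),
          ph = pr$ph_base + pr$ph_per_hot_day * hot30 +
            stats::rnorm(1, 0, pr$ph_sd),
          hot30_days = hot30
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Configuration for the phytosanitary treatment simulator
#'
#' @param n0 Expected total treatments in the first year (must be >= 1).
#' @param growth_rate Exponential growth rate per year (>= 0).
#' @param split_downy Fraction of treatments directed against downy mildew.
#' @param seed Integer RNG seed.
#' @return A validated list of class `treatment_sim_config`.
#' @export
treatment_sim_config <- function(n0 = 6, growth_rate = 0.15,
                                 split_downy = 0.6, seed = 42) {
  if (n0 < 1) stop("n0 must be >= 1", call. = FALSE)
  if (growth_rate < 0) stop("growth_rate must be >= 0", call. = FALSE)
  if (split_downy < 0 || split_downy > 1) {
    stop("split_downy must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n0 = n0, growth_rate = growth_rate, split_downy = split_downy,
         seed = as.integer(seed)),
    class = "treatment_sim_config"
  )
}

#' Simulate annual phytosanitary treatment counts
#'
#' Annual totals are Poisson with mean `n0 * exp(growth_rate * t)` where
#' `t` counts years from the first requested year; each treatment is
#' directed against downy mildew with probability `split_downy`, the rest
#' against powdery mildew.
#'
#' @param config A [treatment_sim_config()].
#' @param years Integer vector of years.
#' @return A tibble: `year`, `downy_mildew_n`, `powdery_mildew_n`,
#'   `total_n`.
#' @export
simulate_treatments <- function(config, years) {
  stopifnot(inherits(config, "treatment_sim_config"))
  years <- as.integer(years)
  withr::with_seed(config$seed, {
    t <- years - min(years)
    lambda <- config$n0 * exp(config$growth_rate * t)
    total <- stats::rpois(length(years), lambda)
    downy <- stats::rbinom(length(years), total, config$split_downy)
    tibble::tibble(
      year = years,
      downy_mildew_n = downy,
      powdery_mildew_n = total - downy,
      total_n = total
    )
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes the full input set the pipeline consumes: two
#' station weather files (a western station covering 1995-2015 and an
#' eastern one covering 2004-2015, mirroring the unbalanced white/red
#' records the analysis is designed for), a phenology/quality table for
#' the seven default varieties, annual treatment counts for 2000-2015,
#' and the resolved generating configuration. Output is byte-stable for a
#' given `master_seed`: the master seed fans out deterministically to
#' per-component child seeds.
#'
#' @param out_dir Output directory (created if needed).
#' @param master_seed Integer master seed.
#' @return Invisibly, a named list of the file paths written
#'   (`weather_west`, `weather_east`, `pheno`, `treatments`, `config`).
#' @export
make_fixture_bundle <- function(out_dir, master_seed = 42) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seed <- as.integer(master_seed)
  child <- function(k) (master_seed * 7L + k * 1009L) %% 2147483647L

  cfg_west <- weather_sim_config(years = 1995:2015, seed = child(1L))
  cfg_east <- weather_sim_config(years = 2004:2015, seed = child(2L))
  west <- simulate_weather(cfg_west, station_id = "west")
  east <- simulate_weather(cfg_east, station_id = "east")

  profiles <- genotype_profiles()
  pheno_w <- simulate_phenology_quality(
    west, profiles[profiles$group == "white", ], seed = child(3L))
  pheno_e <- simulate_phenology_quality(
    east, profiles[profiles$group == "red", ], seed = child(4L))
  pheno <- dplyr::bind_rows(pheno_w, pheno_e)
  pheno <- pheno[!is.na(pheno$harvest_jd), , drop = FALSE]

  tcfg <- treatment_sim_config(seed = child(5L))
  treatments <- simulate_treatments(tcfg, 2000:2015)

  fmt_weather <- function(s) {
    data.frame(date = format(s$date, "%Y-%m-%d"),
               tmin = round(s$tmin, 2), tmax = round(s$tmax, 2),
               tmean = round(s$tmean, 2), precip = round(s$precip, 2))
  }
  paths <- list(
    weather_west = file.path(out_dir, "weather_west.csv"),
    weather_east = file.path(out_dir, "weather_east.csv"),
    pheno = file.path(out_dir, "pheno.csv"),
    treatments = file.path(out_dir, "treatments.csv"),
    config = file.path(out_dir, "sim_config_resolved.yaml")
  )
  readr::write_csv(fmt_weather(west), paths$weather_west)
  readr::write_csv(fmt_weather(east), paths$weather_east)
  readr::write_csv(
    data.frame(variety = pheno$variety, year = pheno$year,
               harvest_date = format(pheno$harvest_date, "%Y-%m-%d"),
               tss = round(pheno$tss, 2), ta = round(pheno$ta, 2),
               ph = round(pheno$ph, 2)),
    paths$pheno
  )
  readr::write_csv(
    data.frame(year = treatments$year, downy = treatments$downy_mildew_n,
               powdery = treatments$powdery_mildew_n),
    paths$treatments
  )
  yaml::write_yaml(
    list(master_seed = master_seed,
         weather_west = unclass(cfg_west),
         weather_east = unclass(cfg_east),
         treatments = unclass(tcfg),
         profiles = as.data.frame(profiles)),
    paths$config
  )
  invisible(paths)
}
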