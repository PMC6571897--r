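test_that("degree-day indices have exact closed forms on constant years", {
  s <- constant_weather_year(2011, tmean = 20)  # tmax = 25, tmin = 15
  expect_equal(winkler_index(s, 2011), (20 - 10) * 214, tolerance = 1e-12)
  expect_equal(winkler_index(constant_weather_year(2011, tmean = 10), 2011), 0)

  # Huglin: tmean = tmax = 20 via zero upper spread
  s20 <- constant_weather_year(2011, tmean = 20, tmax = 20, tmin = 15)
  expect_equal(huglin_index(s20, 2011, d = 1.03), 183 * 10 * 1.03,
               tolerance = 1e-12)
  # same daily mean of the two excess terms
  s_asym <- constant_weather_year(2011, tmean = 15, tmax = 25, tmin = 10)
  expect_equal(huglin_index(s_asym, 2011, d = 1.03), 1884.9,
               tolerance = 1e-9)

  expect_equal(cool_night_index(constant_weather_year(2011, tmin = 12,
                                                      tmean = 17), 2011), 12)
  expect_equal(gst(constant_weather_year(2011, tmean = 19.6), 2011), 19.6)
  expect_equal(lgs(constant_weather_year(2011, tmean = 9), 2011), 0)
})

test_that("huglin_index validates the day-length coefficient", {
  s <- constant_weather_year(2011, tmean = 20)
  expect_error(huglin_index(s, 2011, d = 1.2), "1.00, 1.06")
  expect_error(huglin_index(s, 2011, d = 0.9), "1.00, 1.06")
})

test_that("all indices agree with brute-force loop oracles", {
  for (seed in 1:8) {
    r <- random_weather_year(2000 + seed, seed = seed)
    y <- 2000 + seed
    expect_equal(winkler_index(r, y), oracle_winkler(r, y), tolerance = 1e-9)
    expect_equal(winkler_index(r, y, clip_negative = FALSE),
                 oracle_winkler(r, y, clip = FALSE), tolerance = 1e-9)
    expect_equal(huglin_index(r, y), oracle_huglin(r, y), tolerance = 1e-9)
    expect_equal(cool_night_index(r, y), oracle_ci(r, y), tolerance = 1e-9)
    expect_equal(gst(r, y), oracle_gst(r, y), tolerance = 1e-9)
    expect_equal(lgs(r, y), oracle_lgs(r, y))
    expect_equal(htc(r, y), oracle_htc(r, y), tolerance = 1e-9)
    expect_equal(
      threshold_days(r, y, NULL, "tmin", "<=", 0),
      oracle_threshold(r, y, 1, 1, 12, 31, "tmin", "<=", 0))
    expect_equal(
      threshold_days(r, y, season_window("winkler_window"), "tmax", ">=", 30),
      oracle_threshold(r, y, 4, 1, 10, 31, "tmax", ">=", 30))
  }
})

test_that("threshold comparisons are inclusive", {
  s <- constant_weather_year(2011, tmean = 25, tmax = 30, tmin = 20)
  w <- season_window("huglin_window")  # 183 days
  expect_equal(threshold_days(s, 2011, w, "tmax", ">=", 30), 183)
  s2 <- constant_weather_year(2011, tmean = 5.5, tmin = 0.5, tmax = 10.5)
  expect_equal(threshold_days(s2, 2011, w, "tmin", "<=", 0), 0)
})

test_that("uniform warming moves indices monotonically", {
  r <- random_weather_year(2005, seed = 21)
  warmer <- daily_weather_series(
    data.frame(date = r$date, tmin = r$tmin + 2, tmax = r$tmax + 2,
               tmean = r$tmean + 2, precip = r$precip))
  y <- 2005
  expect_gte(winkler_index(warmer, y), winkler_index(r, y))
  expect_gte(huglin_index(warmer, y), huglin_index(r, y))
  expect_gte(gst(warmer, y), gst(r, y))
  expect_gte(lgs(warmer, y), lgs(r, y))
  gw <- season_window("winkler_window")
  expect_gte(threshold_days(warmer, y, gw, "tmax", ">=", 25),
             threshold_days(r, y, gw, "tmax", ">=", 25))
  expect_lte(threshold_days(warmer, y, NULL, "tmin", "<=", 0),
             threshold_days(r, y, NULL, "tmin", "<=", 0))
})

test_that("a +1 degree shift adds exactly one degree-day per window day", {
  s <- constant_weather_year(2011, tmean = 15)  # all days above base
  plus1 <- constant_weather_year(2011, tmean = 16)
  expect_equal(winkler_index(plus1, 2011) - winkler_index(s, 2011), 214,
               tolerance = 1e-9)
})

test_that("Huglin reduces to the scaled Apr-Sep degree-day sum when tmax = tmean", {
  r <- random_weather_year(2007, seed = 33)
  flat <- daily_weather_series(
    data.frame(date = r$date, tmin = r$tmin, tmax = r$tmean,
               tmean = r$tmean, precip = r$precip))
  apr_sep <- flat$date >= as.Date("2007-04-01") &
    flat$date <= as.Date("2007-09-30")
  expect_equal(huglin_index(flat, 2007, d = 1.03),
               1.03 * sum(pmax(0, flat$tmean[apr_sep] - 10)),
               tolerance = 1e-9)
})

test_that("HTC closed form, zero-precip case and degenerate error", {
  s <- constant_weather_year(2011, tmean = 20, precip = 2)  # 366 mm Apr-Sep
  expect_equal(htc(s, 2011), 10 * (183 * 2) / 1830, tolerance = 1e-12)
  expect_equal(htc(constant_weather_year(2011, tmean = 20, precip = 0),
                   2011), 0)
  expect_error(htc(constant_weather_year(2011, tmean = 8), 2011),
               "degree-day sum is zero")
})

test_that("pre-harvest maximum temperature uses the trailing 30-day window", {
  s <- constant_weather_year(2011, tmean = 26, tmax = 31, tmin = 21)
  expect_equal(max_temp_prior_to_harvest(s, as.Date("2011-09-15")), 31)

  r <- constant_weather_year(2011, tmean = 26, tmax = 31, tmin = 21)
  r$tmax[r$date == as.Date("2011-09-10")] <- 38  # spike at harvest - 5
  s2 <- daily_weather_series(as.data.frame(r[, -which(names(r) == "tmean")]))
  expect_equal(max_temp_prior_to_harvest(s2, as.Date("2011-09-15")), 38)
  # spike outside the window is invisible
  expect_equal(max_temp_prior_to_harvest(s2, as.Date("2011-08-09")), 31)
  # calendar-month mode scans the previous full month
  expect_equal(max_temp_prior_to_harvest(s2, as.Date("2011-09-15"),
                                         mode = "calendar"), 31)
  expect_equal(max_temp_prior_to_harvest(s2, as.Date("2011-10-05"),
                                         mode = "calendar"), 38)
})

test_that("classify anchors, boundary rule and exhaustive agreement", {
  tab <- gst_maturity_table()
  expect_equal(classify(19.6, tab), "hot")
  expect_equal(classify(17.0, tab), "warm")    # boundary -> upper class
  expect_equal(classify(13.0, tab), "cool")
  expect_equal(classify(-40, tab), "too cool")
  expect_equal(classify(40, tab), "too hot")

  # exhaustive scan vs a brute-force interval search
  brute <- function(v) {
    for (i in seq_len(nrow(tab))) {
      if (v >= tab$lower[i] && v < tab$upper[i]) return(tab$label[i])
    }
  }
  grid <- seq(5, 30, by = 0.25)  # includes every boundary
  expect_equal(classify(grid, tab), vapply(grid, brute, character(1)))
  # idempotent over repeated application of the boundary rule
  expect_equal(classify(grid, tab), classify(grid, tab))
})

test_that("class tables enforce their interval invariants", {
  expect_error(class_boundary_table("x", c("a", "b"), c(1, 2)), "exactly")
  expect_error(class_boundary_table("x", c("a", "b", "c"), c(2, 1)),
               "strictly increasing")
  tab <- wi_region_table()
  expect_equal(tab$upper[-nrow(tab)], tab$lower[-1])  # contiguous cover
})

test_that("ombrothermic profile flags dry months by the 2t rule", {
  mon <- tibble::tibble(year = 2000, month = c(7, 11),
                        mean_t = c(25, 10), total_p = c(40, 100),
                        n_days = c(31, 30))
  pr <- ombrothermic_profile(mon)
  expect_true(pr$dry[pr$month == 7])     # 40 < 2 * 25
  expect_false(pr$dry[pr$month == 11])   # 100 > 2 * 10
  expect_error(ombrothermic_profile(mon, period = 1980), "no monthly")
})

test_that("compute_index_set marks uncovered windows absent, not zero", {
  s <- constant_weather_year(2011, tmean = 20, precip = 2)
  idx <- compute_index_set(s, 2011)
  expect_equal(idx$wi, 2140)
  expect_equal(idx$gst, 20)
  expect_equal(idx$ci, 15)
  expect_equal(idx$lgs, 365)
  expect_equal(idx$hot25_days, 214)
  expect_equal(idx$hot30_days, 0)
  expect_equal(idx$frost_days, 0)
  expect_equal(idx$htc, 2, tolerance = 1e-12)

  # September removed: with a threshold just below the remaining coverage
  # the cool-night index is absent while year/window indices survive
  keep <- format(s$date, "%m") != "09"
  s2 <- daily_weather_series(as.data.frame(s[keep, ]))
  idx2 <- compute_index_set(s2, 2011, min_coverage = 0.85)
  expect_true(is.na(idx2$ci))
  expect_false(is.na(idx2$wi))
  expect_false(is.na(idx2$gst))
  expect_false(is.na(idx2$lgs))
})

test_that("index set equals per-index functions on random years", {
  for (seed in c(3, 14)) {
    y <- 2009
    r <- random_weather_year(y, seed = seed)
    idx <- compute_index_set(r, y)
    expect_equal(idx$wi, winkler_index(r, y))
    expect_equal(idx$hi, huglin_index(r, y))
    expect_equal(idx$ci, cool_night_index(r, y))
    expect_equal(idx$gst, gst(r, y))
    expect_equal(idx$lgs, lgs(r, y))
    expect_equal(idx$htc, htc(r, y))
    expect_equal(idx$rainy_days, oracle_rainy(r, y))
    expect_true(idx$hot30_days <= idx$hot25_days)
    expect_true(idx$ice_days <= idx$frost_days)
  }
})
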