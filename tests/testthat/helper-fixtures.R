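# Fixture builders and brute-force oracles, independent of the package's
# own accumulation code: every oracle is a plain day-by-day loop or a
# closed form.

# A full random calendar year, built directly (not via simulate_weather)
# so that index oracles are checked against an independent input path.
random_weather_year <- function(year, seed) {
  set.seed(seed)
  d <- seq(as.Date(sprintf("%04d-01-01", year)),
           as.Date(sprintf("%04d-12-31", year)), by = "day")
  doy <- as.integer(format(d, "%j"))
  tmean <- 13 + 10 * sin(2 * pi * (doy - 110) / 365.25) + rnorm(length(d), 0, 3)
  spread_lo <- runif(length(d), 2, 7)
  spread_hi <- runif(length(d), 2, 7)
  precip <- ifelse(runif(length(d)) < 0.3, rgamma(length(d), 0.8, scale = 9), 0)
  daily_weather_series(
    data.frame(date = d, tmin = tmean - spread_lo, tmax = tmean + spread_hi,
               tmean = tmean, precip = precip),
    station_id = paste0("rand", seed)
  )
}

# Subset a series to one calendar year (plain data frame, keeps columns).
one_year <- function(s, year) {
  s[format(s$date, "%Y") == as.character(year), , drop = FALSE]
}

# Day-by-day loop oracles -----------------------------------------------

window_bounds <- function(year, m1, d1, m2, d2) {
  c(as.Date(sprintf("%04d-%02d-%02d", year, m1, d1)),
    as.Date(sprintf("%04d-%02d-%02d", year, m2, d2)))
}

oracle_winkler <- function(s, year, clip = TRUE) {
  b <- window_bounds(year, 4, 1, 10, 31)
  acc <- 0
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2]) {
      dd <- s$tmean[i] - 10
      if (clip && dd < 0) dd <- 0
      acc <- acc + dd
    }
  }
  acc
}

oracle_huglin <- function(s, year, d = 1.03, clip = TRUE) {
  b <- window_bounds(year, 4, 1, 9, 30)
  acc <- 0
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2]) {
      dd <- ((s$tmean[i] - 10) + (s$tmax[i] - 10)) / 2
      if (clip && dd < 0) dd <- 0
      acc <- acc + dd
    }
  }
  d * acc
}

oracle_ci <- function(s, year) {
  b <- window_bounds(year, 9, 1, 9, 30)
  v <- c()
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2]) v <- c(v, s$tmin[i])
  }
  mean(v)
}

oracle_gst <- function(s, year) {
  b <- window_bounds(year, 4, 1, 10, 31)
  v <- c()
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2]) v <- c(v, s$tmean[i])
  }
  mean(v)
}

oracle_lgs <- function(s, year) {
  b <- window_bounds(year, 1, 1, 12, 31)
  cnt <- 0
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2] && s$tmean[i] > 10) {
      cnt <- cnt + 1
    }
  }
  cnt
}

oracle_threshold <- function(s, year, m1, d1, m2, d2, var, op, thr) {
  b <- window_bounds(year, m1, d1, m2, d2)
  cnt <- 0
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2]) {
      v <- s[[var]][i]
      hit <- if (op == ">=") v >= thr else v <= thr
      if (hit) cnt <- cnt + 1
    }
  }
  cnt
}

oracle_htc <- function(s, year) {
  b <- window_bounds(year, 4, 1, 9, 30)
  p <- 0; dd <- 0
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2]) {
      p <- p + s$precip[i]
      dd <- dd + max(0, s$tmean[i] - 10)
    }
  }
  10 * p / dd
}

oracle_rainy <- function(s, year, thr = 1) {
  b <- window_bounds(year, 1, 1, 12, 31)
  cnt <- 0
  for (i in seq_len(nrow(s))) {
    if (s$date[i] >= b[1] && s$date[i] <= b[2] && s$precip[i] > thr) {
      cnt <- cnt + 1
    }
  }
  cnt
}

# Closed-form statistics oracles ----------------------------------------

# OLS slope/intercept/r2/p via the normal equations and t-transform.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  ssr <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - ssr / sst
  se <- sqrt(ssr / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, r2 = r2,
       p = 2 * pt(-abs(tval), n - 2))
}

# Pearson r via the covariance formula; p via the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), n - 2))
}
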