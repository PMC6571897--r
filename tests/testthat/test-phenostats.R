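test_that("linear_trend recovers exact and degenerate fits", {
  x <- 2000:2010
  tr <- linear_trend(x, 2 * x + 3)
  expect_equal(tr$slope, 2)
  expect_equal(tr$intercept, 3)
  expect_equal(tr$r2, 1)
  expect_equal(tr$model, "linear")

  flat <- linear_trend(x, rep(7, length(x)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  expect_error(linear_trend(1:2, 1:2), "at least 3")
  expect_error(linear_trend(c(1, 1, 1), c(1, 2, 3)), "strictly increasing")
})

test_that("linear_trend matches the normal-equation oracle", {
  set.seed(91)
  for (i in 1:5) {
    x <- 1995:2015
    y <- 0.3 * x + rnorm(21, 0, 4)
    tr <- linear_trend(x, y)
    or <- oracle_ols(x, y)
    expect_equal(tr$slope, or$slope, tolerance = 1e-9)
    expect_equal(tr$intercept, or$intercept, tolerance = 1e-9)
    expect_equal(tr$r2, or$r2, tolerance = 1e-9)
    expect_equal(tr$p_value, or$p, tolerance = 1e-9)
  }
})

test_that("exponential_trend is log-linear OLS with an nls option", {
  x <- 0:15
  tr <- exponential_trend(x, 2 * exp(0.1 * x))
  expect_equal(tr$slope, 0.1, tolerance = 1e-9)
  expect_equal(tr$r2, 1)
  expect_equal(tr$model, "exponential")

  expect_equal(exponential_trend(x, rep(5, 16))$slope, 0)
  expect_error(exponential_trend(x, c(rep(2, 15), 0)), "positive")

  set.seed(8)
  y <- rpois(16, 6 * exp(0.15 * x))
  y[y == 0] <- 1
  a <- exponential_trend(x, y)
  b <- exponential_trend(x, y, method = "nls")
  expect_equal(a$slope, b$slope, tolerance = 0.05)
})

test_that("pearson_screen matches closed-form r and t-transform p", {
  set.seed(17)
  for (k in 1:5) {
    m <- matrix(rnorm(20 * 4), 20, 4,
                dimnames = list(NULL, letters[1:4]))
    cm <- pearson_screen(m)
    for (i in 1:3) for (j in (i + 1):4) {
      or <- oracle_pearson(m[, i], m[, j])
      expect_equal(cm$r[i, j], or$r, tolerance = 1e-9)
      expect_equal(cm$p[i, j], or$p, tolerance = 1e-9)
      expect_equal(cm$significant[i, j], or$p < 0.05)
    }
    expect_equal(cm$r, t(cm$r))
    expect_equal(unname(diag(cm$r)), rep(1, 4))
  }
})

test_that("pearson_screen handles perfect, constant and adjusted cases", {
  x <- rnorm(12)
  cm <- pearson_screen(data.frame(a = x, b = x, c = -x))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_true(all(cm$significant[upper.tri(cm$significant)]))

  cm2 <- pearson_screen(data.frame(a = x, k = rep(2, 12)))
  expect_equal(cm2$constant_variables, "k")
  expect_true(is.na(cm2$r["a", "k"]))
  expect_false(cm2$significant["a", "k"])

  # BH adjustment can only reduce the significant set
  set.seed(5)
  m <- matrix(rnorm(15 * 6), 15, 6)
  raw <- pearson_screen(m)
  adj <- pearson_screen(m, p_adjust = "BH")
  expect_true(all(adj$significant <= raw$significant))
})

test_that("run_pca equals the eigen-decomposition of the correlation matrix", {
  set.seed(23)
  for (k in 1:5) {
    n <- sample(8:15, 1); p <- sample(3:6, 1)
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    res <- run_pca(m)
    eg <- eigen(cor(m), symmetric = TRUE)
    expect_equal(res$eigenvalues, eg$values, tolerance = 1e-9)
    for (j in seq_len(ncol(res$loadings))) {
      v <- eg$vectors[, j]
      # compare up to sign
      expect_equal(abs(res$loadings[, j]), abs(v), tolerance = 1e-8,
                   ignore_attr = TRUE)
      # documented sign convention: largest-|loading| entry positive
      expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
    }
    expect_equal(sum(res$explained_variance), 1, tolerance = 1e-9)
    expect_true(all(diff(res$explained_variance) <= 1e-12))
    # scores: zero mean, diagonal covariance carrying the eigenvalues
    expect_equal(colMeans(res$scores), rep(0, p), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(cov(res$scores), diag(res$eigenvalues), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("run_pca degenerate inputs", {
  x <- rnorm(10)
  res <- run_pca(data.frame(a = x, b = 2 * x + 1))
  expect_equal(res$explained_variance[1], 1, tolerance = 1e-9)

  expect_error(run_pca(data.frame(a = x, k = rep(1, 10))), "k")
  expect_error(run_pca(data.frame(a = c(x, NA), b = c(2 * x, 1))), "missing")
})

test_that("biplot_quadrants follows the sign table with zeros positive", {
  set.seed(3)
  m <- matrix(rnorm(30 * 4), 30, 4)
  res <- run_pca(m)
  q <- biplot_quadrants(res, c(1, 2))
  sx <- res$scores[, 1] >= 0; sy <- res$scores[, 2] >= 0
  expected <- ifelse(sx & sy, "I", ifelse(!sx & sy, "II",
                     ifelse(!sx & !sy, "III", "IV")))
  expect_equal(q, expected)

  res$scores[1, 1:2] <- c(1, 1); res$scores[2, 1:2] <- c(2, -3)
  res$scores[3, 1:2] <- c(0, 0)
  q2 <- biplot_quadrants(res)
  expect_equal(q2[1:3], c("I", "IV", "I"))
  expect_error(biplot_quadrants(res, c(1, 9)), "not retained")
})

test_that("variety_climate_report joins, fits and skips correctly", {
  set.seed(44)
  years <- 2000:2014
  idx <- tibble::tibble(
    year = years,
    wi = 1900 + 10 * (years - 2000) + rnorm(15, 0, 30),
    hi = 2100 + rnorm(15, 0, 30),
    gst = 18 + rnorm(15, 0, 0.3),
    ci = 13 + rnorm(15, 0, 0.5),
    hot30_days = rpois(15, 10),
    growing_p = 600 + rnorm(15, 0, 50))
  pheno <- tibble::tibble(
    variety = rep(c("CH", "XX"), c(15, 2)),
    year = c(years, 2000:2001),
    harvest_jd = c(260 - 0.8 * (years - 2000) + rnorm(15, 0, 2), 250, 251),
    tss = c(20 + rnorm(15, 0, 0.3), 20, 20),
    ta = c(9 - 0.08 * idx$hot30_days + rnorm(15, 0, 0.2), 7, 7),
    ph = 3.2 + c(rnorm(15, 0, 0.05), 0, 0))
  expect_warning(rep <- variety_climate_report(pheno, idx), "XX")
  expect_setequal(unique(rep$trends$variety), "CH")
  jd_tr <- rep$trends[rep$trends$response == "harvest_jd", ]
  expect_lt(jd_tr$slope, 0)
  expect_lt(jd_tr$p_value, 0.05)
  cm <- rep$correlations$CH
  expect_lt(cm$r["ta", "hot30_days"], 0)
  expect_true(cm$significant["ta", "hot30_days"])
})
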