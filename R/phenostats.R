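#' Ordinary least-squares linear trend
#'
#' Fits `y = intercept + slope * x` by OLS and reports the two-sided
#' p-value for a non-zero slope. Used for ripening-date, quality and
#' climate-index trends against vintage year.
#'
#' @param x Numeric predictor (typically years), strictly increasing.
#' @param y Numeric response.
#' @return A `trend_result` list: `slope` (units/year when `x` is years),
#'   `intercept`, `r2`, `p_value`, `n`, `model = "linear"`.
#' @export
linear_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("linear_trend needs at least 3 observations", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # exact fits trip summary.lm's "perfect fit" warning; that case is
  # handled explicitly below
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  p_value <- if (sm$sigma == 0) {
    # exact fit: slope test degenerates; p = 0 if slope != 0 else 1
    if (abs(slope) > 0) 0 else 1
  } else {
    unname(sm$coefficients[2, 4])
  }
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r2 = if (stats::var(y) == 0) 0 else sm$r.squared,
         p_value = p_value,
         n = n,
         model = "linear"),
    class = "trend_result"
  )
}

#' Exponential growth trend via log-linear regression
#'
#' Fits `ln(y) = a + r * x` by OLS; `r` is the per-unit-of-x relative
#' growth rate and `r2` is reported on the log scale. Used for
#' phytosanitary treatment counts that grow multiplicatively. A nonlinear
#' least-squares refinement of the same model is available for comparison.
#'
#' @param x Numeric predictor (years).
#' @param y Positive counts or amounts; zero or negative values are an
#'   error (offset counts explicitly before calling if needed).
#' @param method `"loglinear"` (default) or `"nls"` (nonlinear least
#'   squares on the original scale, started from the log-linear fit).
#' @return A `trend_result` list with `slope` = growth rate per unit x,
#'   `intercept` = `ln(y)` at `x = 0`, `r2`, `p_value`, `n`,
#'   `model = "exponential"`.
#' @export
exponential_trend <- function(x, y, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(y) < 3) {
    stop("exponential_trend needs at least 3 observations", call. = FALSE)
  }
  if (any(y <= 0)) {
    stop("exponential_trend requires strictly positive y; ",
         "offset counts explicitly if zeros are expected", call. = FALSE)
  }
  ll <- linear_trend(x, log(y))
  if (method == "nls") {
    fit <- stats::nls(y ~ exp(a + r * x),
                      start = list(a = ll$intercept, r = ll$slope))
    co <- stats::coef(fit)
    ll$intercept <- unname(co["a"])
    ll$slope <- unname(co["r"])
    ll$p_value <- summary(fit)$coefficients["r", 4]
  }
  ll$model <- "exponential"
  ll
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> %s: slope %.4g, r2 %.3f, p %.3g (n = %d)\n",
    x$model, x$slope, x$r2, x$p_value, x$n))
  invisible(x)
}

#' Pairwise Pearson correlation screen
#'
#' Computes Pearson r and two-sided p-values for every pair of variables
#' using pairwise-complete observations, and flags pairs significant at
#' level `alpha`. No multiplicity correction is applied by default, as is
#' common in exploratory climate-quality screening; set
#' `p_adjust = "BH"` for Benjamini-Hochberg adjusted significance.
#'
#' @param table A data frame or matrix of numeric variables (observations
#'   in rows).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return A `correlation_matrix` list with square matrices `r`, `p`,
#'   `n` (pairwise sample sizes), a logical `significant` mask at `alpha`,
#'   and `constant_variables` naming columns with zero variance (their
#'   pairs are `NA` and never significant).
#' @export
pearson_screen <- function(table, alpha = 0.05, p_adjust = "none") {
  m <- as.matrix(as.data.frame(table))
  storage.mode(m) <- "double"
  vars <- colnames(m)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(m)))
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  nmat <- matrix(0L, k, k, dimnames = list(vars, vars))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  constant <- vars[!is.na(sds) & sds == 0]
  for (i in seq_len(k)) {
    r[i, i] <- 1; p[i, i] <- 0
    nmat[i, i] <- sum(!is.na(m[, i]))
    for (j in seq_len(k)) {
      if (j <= i) next
      ok <- stats::complete.cases(m[, i], m[, j])
      nij <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nij
      if (nij < 3 || vars[i] %in% constant || vars[j] %in% constant) next
      if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) next
      ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  p_for_mask <- p
  if (p_adjust != "none") {
    up <- upper.tri(p)
    adj <- stats::p.adjust(p[up], method = p_adjust)
    p_for_mask[up] <- adj
    p_for_mask[lower.tri(p_for_mask)] <-
      t(p_for_mask)[lower.tri(p_for_mask)]
  }
  sig <- !is.na(p_for_mask) & p_for_mask < alpha
  diag(sig) <- FALSE
  structure(
    list(variables = vars, r = r, p = p, n = nmat, significant = sig,
         alpha = alpha, p_adjust = p_adjust,
         constant_variables = constant),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf(
    "<correlation_matrix> %d variables, %d significant pair(s) at alpha = %g\n",
    length(x$variables), sum(x$significant) / 2, x$alpha))
  print(round(x$r, 3))
  invisible(x)
}

#' Standardised principal component analysis
#'
#' PCA on variables standardised to zero mean and unit variance
#' (equivalently, an eigen-analysis of the correlation matrix) — the
#' appropriate choice when variables mix degrees C, degree-days, mm and
#' degrees Brix. Components are ordered by decreasing eigenvalue and a
#' deterministic sign convention is applied: within each component the
#' largest-magnitude loading is made positive, so results are reproducible
#' across eigen-solvers.
#'
#' @param table A data frame or matrix of numeric variables, no missing
#'   values (listwise-delete before calling).
#' @param n_components Number of components to retain (default: all).
#' @return A `pca_result` list: `loadings` (variables x components),
#'   `scores` (observations x components), `explained_variance` (fraction
#'   per retained component), `cumulative_variance`, `eigenvalues` (all
#'   components), `center`, `scale`.
#' @export
run_pca <- function(table, n_components = NULL) {
  m <- as.matrix(as.data.frame(table))
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    stop("run_pca does not accept missing values; filter rows first",
         call. = FALSE)
  }
  if (nrow(m) < 3) stop("run_pca needs at least 3 observations", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  k_all <- ncol(pc$rotation)
  if (is.null(n_components)) n_components <- k_all
  n_components <- min(n_components, k_all)

  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(n_components)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- pc$sdev^2
  expl <- eig / sum(eig)
  structure(
    list(loadings = loadings,
         scores = scores,
         explained_variance = expl[seq_len(n_components)],
         cumulative_variance = cumsum(expl)[seq_len(n_components)],
         eigenvalues = eig,
         center = pc$center,
         scale = pc$scale),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d components retained; cumulative variance %.1f%%\n",
    ncol(x$loadings), 100 * utils::tail(x$cumulative_variance, 1)))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Quadrant labels of PCA scores in a component plane
#'
#' Assigns each observation to a Cartesian quadrant of the chosen
#' component plane by the signs of its scores: I (+,+), II (-,+),
#' III (-,-), IV (+,-). A zero score counts as positive.
#'
#' @param result A [run_pca()] result.
#' @param axis_pair Integer pair: which components span the plane
#'   (default first and second).
#' @return Character vector of quadrant labels `"I"`..`"IV"`.
#' @export
biplot_quadrants <- function(result, axis_pair = c(1, 2)) {
  stopifnot(inherits(result, "pca_result"), length(axis_pair) == 2)
  if (max(axis_pair) > ncol(result$scores)) {
    stop("requested component not retained in the PCA result", call. = FALSE)
  }
  sx <- result$scores[, axis_pair[1]] >= 0
  sy <- result$scores[, axis_pair[2]] >= 0
  dplyr::case_when(
    sx & sy ~ "I",
    !sx & sy ~ "II",
    !sx & !sy ~ "III",
    TRUE ~ "IV"
  )
}

#' Per-variety climate-quality report
#'
#' Joins phenology/quality records with annual bioclimatic index sets and,
#' for each variety with enough overlapping years, fits linear trends of
#' harvest day, total soluble solids and titratable acidity against year
#' and screens Pearson correlations of the quality variables against the
#' thermal indices.
#'
#' @param pheno A tibble of phenology/quality records with columns
#'   `variety`, `year`, `harvest_jd`, `tss`, `ta`, `ph`.
#' @param indices A tibble of annual index sets as returned by
#'   [compute_index_set()] (one row per year), including `growing_p` —
#'   growing-season precipitation — if available (added automatically by
#'   the pipeline).
#' @param alpha Significance level for the correlation screen.
#' @param min_years Minimum overlapping years per variety (default 3);
#'   varieties below it are skipped with a warning.
#' @return A list with `trends` (tibble: variety, response, slope, r2,
#'   p_value, n), `correlations` (named list of `correlation_matrix` per
#'   variety) and `joined` (the merged analysis table).
#' @export
variety_climate_report <- function(pheno, indices, alpha = 0.05,
                                   min_years = 3) {
  index_vars <- intersect(
    c("wi", "hi", "gst", "ci", "hot30_days", "growing_p"),
    names(indices)
  )
  joined <- dplyr::inner_join(pheno, indices, by = "year")
  trends <- list()
  correlations <- list()
  for (v in unique(joined$variety)) {
    sub <- joined[joined$variety == v, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    n_ok <- sum(stats::complete.cases(sub[, c("year", "harvest_jd")]))
    if (n_ok < min_years) {
      warning("variety ", v, " skipped: only ", n_ok,
              " overlapping year(s)", call. = FALSE)
      next
    }
    for (resp in c("harvest_jd", "tss", "ta")) {
      tr <- tryCatch(linear_trend(sub$year, sub[[resp]]),
                     error = function(e) NULL)
      if (is.null(tr)) next
      trends[[length(trends) + 1]] <- tibble::tibble(
        variety = v, response = resp, slope = tr$slope, r2 = tr$r2,
        p_value = tr$p_value, n = tr$n
      )
    }
    correlations[[v]] <- pearson_screen(
      sub[, c("tss", "ta", "ph", "harvest_jd", index_vars)],
      alpha = alpha
    )
  }
  list(
    trends = if (length(trends)) dplyr::bind_rows(trends) else
      tibble::tibble(variety = character(), response = character(),
                     slope = double(), r2 = double(), p_value = double(),
                     n = integer()),
    correlations = correlations,
    joined = joined
  )
}
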