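---
title: "Methods: bioclimatic indices, climate-quality statistics and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioclimatic indices, climate-quality statistics and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitibioclim)
```

## Scope and data model

`vitibioclim` analyses the climate of a grape-growing site and its
relationship to grapevine ripening, berry quality and disease-treatment
pressure. The sole climate input is a *daily weather series*: a
date-ordered table of Tmin, Tmax, Tmean (°C) and precipitation (mm),
validated on construction (strictly increasing dates, Tmin ≤ Tmean ≤
Tmax, non-negative precipitation). When a file carries no Tmean column
the package reconstructs it as (Tmin + Tmax)/2 — the standard
convention — and records that imputation in the series provenance so
downstream index values are traceable to it.

All index windows are closed calendar-date intervals. Four windows
recur: the growing season (May 1–Oct 31), the off-season "hydrological
winter" (Nov 1–Apr 30), the Winkler accumulation window (Apr 1–Oct 31)
and the Huglin window (Apr 1–Sep 30), northern-hemisphere conventions
throughout. The off-season preceding a growing season is attributed to
that vintage (November of the previous calendar year through April), so
the winter rain that recharges soil water is credited to the harvest it
supports.

### Missing data

The package does no gap-filling. Every windowed computation takes a
completeness threshold, defaulting to 90% of window days present;
below it the computation refuses with a coverage error rather than
silently extrapolating. In the assembled per-vintage index set, an
index whose window fails coverage is reported absent (`NA`), never
zero — a zero degree-day sum is a real climate statement, absence is
not.

## The index suite

* **Winkler index**: Σ max(0, Tmean − 10 °C) over Apr–Oct. Negative
  daily excesses are clipped at zero, the Winkler convention; the
  clipping is a config switch (`clip_negative`) because some historical
  series were processed without it, and the difference only matters in
  years with cold April/October days.
* **Huglin index**: d · Σ max(0, ((Tmean − 10) + (Tmax − 10))/2) over
  Apr–Sep, with the day-length coefficient d validated to [1.00, 1.06];
  1.03 is the default appropriate to mid-latitude (~42–44° N) sites.
* **GST** is the Apr–Oct mean temperature; **LGS** the count of days in
  the calendar year with Tmean strictly above 10 °C. LGS is reported in
  days: it is defined by a day-count formula even though some published
  tabulations label its unit as degree-days, and we follow the formula.
* **Cool-night index**: mean September Tmin.
* **Threshold-day counts** (frost Tmin ≤ 0, ice Tmax ≤ 0, hot
  Tmax ≥ 25, extreme Tmax ≥ 30) use inclusive comparisons, as the
  thresholds are conventionally printed; hot-day counts are evaluated
  over the Apr–Oct growing window, frost and ice days over the calendar
  year.
* **HTC (Selyaninov hydrothermic coefficient)**: 10 · ΣP / ΣDD. Some
  tabulations divide growing-season precipitation by "the Winkler
  index" whose own window runs through October while the precipitation
  sum stops in September. We align both sums to Apr 1–Sep 30 by
  default — the internally consistent Selyaninov formulation — and
  expose `wi_window = "apr_oct"` for the literal mixed-window variant.
  The difference is a few percent in warm climates.
* **Pre-harvest maximum temperature** uses the trailing 30-day window
  ending the day before harvest. Harvest dates move year to year; a
  calendar-month definition would make the statistic jump
  discontinuously when harvest crosses a month boundary. The
  calendar-month mode remains available.
* **Rainy days** use a strict > 1 mm threshold, exposed as a config
  value.

### Classification

Class tables are ordered, contiguous, half-open intervals `[lower,
upper)` covering the real line; a boundary value belongs to the upper
class, so a site exactly at 17 °C GST is "warm", not "intermediate".
The default GST maturity table is too cool < 13, cool 13–15,
intermediate 15–17, warm 17–19, hot 19–21, very hot 21–24, too hot
> 24 °C; Winkler-region, Huglin and cool-night tables from the
multicriteria climate-classification literature ship as replaceable
data. Composite multi-index class bands that some regional studies use
are supported only as user-supplied tables, because no canonical
numeric bounds exist to hard-code.

### Ombrothermic profiles

The ombrothermic profile averages monthly mean temperature and monthly
precipitation totals over a period (typically 20 years) and flags a
month dry when mean precipitation (mm) is below twice the mean
temperature (°C) — the Bagnouls–Gaussen criterion, the standard
graphical dryness diagnostic for Mediterranean climates.

## Statistical layer

Trends are ordinary least squares with the usual t-test on the slope
(`stats::lm` underneath); at least three observations and non-constant
x are required. Exponential growth (treatment counts) is fitted
log-linearly — ln y regressed on year — reporting the growth rate and
r² on the log scale; a nonlinear least-squares refinement on the
original scale is available for comparison. Log-linear fitting requires
strictly positive counts; callers decide explicitly how to treat zeros
(the recovery analyses in this package drop zero-count years, which at
the default simulation intensities affects well under 1% of year-draws
and biases the recovered rate negligibly).

The correlation screen reports pairwise Pearson r with two-sided
p-values on pairwise-complete observations and flags significance at α
(default 0.05) **without** multiplicity correction — matching the
exploratory practice of climate–quality screening studies, where the
screen generates hypotheses rather than confirms them. A
Benjamini–Hochberg option exists and is off by default. Constant
variables yield `NA` correlations, are never flagged significant, and
are named in the result.

PCA is computed on standardised variables (correlation matrix), since
the inputs mix °C, degree-days, mm, °Brix and g/L; covariance PCA would
let the largest-unit variable dominate. Missing values are not
accepted — callers listwise-delete, making row filtering auditable.
Components are ordered by eigenvalue and signed deterministically (the
largest-magnitude loading of each component is made positive) so
results are identical across eigen-solvers and platforms. Biplot
quadrant labels follow score signs with zeros assigned to the positive
side.

The per-variety report joins quality records to annual index sets and
requires at least three overlapping years per variety; shorter records
are skipped with a warning rather than fitted meaninglessly.

## The synthetic study design

The generator exists so the full pipeline can be exercised and
validated without access to proprietary winery records. Its defaults
*are* the study conditions of the package's tests, chosen once as a
realistic central-Italian Csa regime:

* **Temperature**: a sinusoidal seasonal cycle (amplitude 9 °C, peak at
  day 205) around an annual mean of 13.5 °C in the first simulated
  year, a linear warming trend of 0.08 °C/yr, and stationary AR(1)
  daily noise (sd 2.2 °C, autocorrelation 0.7). The AR coefficient
  matters: it produces the multi-day heat spells that drive
  extreme-hot-day counts; white noise would undercount them. The
  seasonal term is centred within each calendar year, so a noise-free,
  trend-free simulation has an annual mean of exactly the configured
  base — a convenient exactness anchor for tests. Over 21 simulated
  years the 0.08 °C/yr trend moves decadal means by ≈0.85 °C, the
  magnitude of observed secular warming in temperate wine regions.
* **Diurnal range** is fixed at 10 °C (Tmax/Tmin sit ±5 °C around
  Tmean). Real ranges vary with season and cloud cover; the analysis
  only needs plausible envelopes for threshold-day counts, and a fixed
  range keeps every temperature identity exact in tests.
* **Precipitation** is Bernoulli–gamma per day with month-specific wet
  probabilities and gamma scales derived from target monthly totals.
  The targets encode a dry-summer regime with wet autumn and spring:
  ~1000 mm/yr on average, June–August restricted dryness (July and
  August ombrothermically dry), and 35–40% of annual precipitation
  falling in the Nov–Apr off-season — which places the wet September
  and October inside the growing season, as in autumn-peaked
  Mediterranean climates.
* **Phenology**: harvest occurs when degree-days (base 10 °C)
  accumulated from April 1 reach a genotype-specific thermal target,
  plus Gaussian day jitter. This is the simplest mechanism consistent
  with climate-maturity grouping and is documented as a stand-in, not a
  physiological claim: real ripening integrates photoperiod, water
  status and crop load. Thermal targets (1330–1520 degree-days) put
  simulated harvests in late August–early October. International
  variety profiles get small jitter (2.5–3 days), so warming produces
  clear harvest-advance trends (~−1 day/yr at these settings);
  autochthonous profiles (Grechetto, Aleatico) get large jitter (9–10
  days) and near-zero sugar response, so their harvest dates fluctuate
  without significant trend — the qualitative contrast repeatedly
  observed between international and local varieties.
* **Quality**: TSS, TA and pH respond linearly to the count of extreme
  hot days, with genotype-specific signs — acidity falls with heat for
  every variety; sugar falls for Cabernet Sauvignon and Sangiovese and
  rises for Cabernet Franc and Merlot. The coefficients (±0.08–0.12
  per hot day, noise sd 0.35) encode only signs and plausible
  magnitudes and are labelled synthetic throughout. One observed
  pattern the mechanism cannot reproduce is a harvest *delay* under
  warming (reported for some red varieties): a pure thermal-time model
  always advances maturity in a warming climate, so that pattern is
  out of the generator's scope.
* **Treatments**: annual totals are Poisson with exponentially growing
  mean (default 6 treatments growing at 0.15/yr, 60% against downy
  mildew) — phenomenological, with no epidemic dynamics.

Determinism is a contract: every simulator output is a pure function of
its configuration including the seed, and the fixture bundle (two
stations with deliberately unbalanced 21- and 12-year coverage, seven
varieties, 16 years of treatments) is byte-stable under a master seed
that fans out to per-component child seeds.

What passing tests on this generator do show: the index algebra, window
handling, statistical machinery and pipeline plumbing are correct, and
the estimators recover known generating parameters without bias. What
they do not show: anything about sensor error, inhomogeneities, missing
patterns or microclimate of real station data, nor real varietal
physiology.

## Numerical and design choices

* Degree-day clipping, the HTC window, the rainy-day threshold, the
  pre-harvest window mode and the completeness threshold are all
  explicit configuration with documented defaults, because published
  tabulations are ambiguous on each and reproducibility requires
  pinning them.
* Validation tolerates 1e-6 °C of Tmin/Tmean/Tmax disorder to absorb
  rounding in delimited files; real violations (sensor swaps) exceed it
  by orders of magnitude.
* Exact-fit regressions (residual variance zero) report p = 0 for a
  non-zero slope and p = 1 otherwise, avoiding 0/0 in the t-statistic;
  constant responses report slope 0 and r² 0.
* `findInterval` implements classification, which lands boundary values
  in the upper class by construction; an exhaustive scan against a
  brute-force interval search pins this behaviour in tests.
* Leap years: windows are calendar-date defined, so window lengths vary
  by one day across years; closed-form test values pin the non-leap
  case (e.g. 214 days in Apr–Oct).

## Problem sizes used in validation

The test suite validates index functions against independent
day-by-day loop oracles on 100 simulated years and 8 independently
constructed random years; correlation and PCA against closed-form and
eigen-decomposition oracles on 20–25 small random matrices; warming and
treatment-growth recovery on 200 Monte-Carlo replicates of the default
21-year and 16-year designs; the trend test's type-I error on 1000 null
replicates; and genotype response directions on 100 seeds. These sizes
give Monte-Carlo standard errors comfortably below the tolerances
asserted and complete in a few minutes on one core.

## Known limitations

* No gap-filling, homogenisation or multi-station interpolation: one
  validated series per sub-area is assumed.
* The evapotranspiration-based dryness index of multicriteria
  classification is out of scope (it needs data the package does not
  model), as are mechanistic phenology forecasting, mixed-effects
  variety×year models and disease epidemiology.
* Vintage-scale composite labels ("too hot", "moderately dry") used in
  some regional studies have no published numeric bounds and are not
  hard-coded; users can supply their own class tables.
* The correlation screen's unadjusted α reproduces exploratory
  practice; treat its flags as hypotheses, or switch on the BH option.
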