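Package: vitibioclim
Title: Bioclimatic Indices and Climate-Phenology Analytics for Viticulture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the standard suite of temperature-based bioclimatic
    indices used to characterise grape-growing climates (Winkler and Huglin
    degree-day indices, growing-season average temperature, cool-night index,
    frost/ice/hot-day counts, and the Selyaninov hydrothermic coefficient)
    from daily weather records, classifies climate regimes against
    configurable class tables, builds ombrothermic (Bagnouls-Gaussen) dryness
    profiles, and links the indices to grapevine ripening phenology, berry
    quality and phytosanitary-treatment pressure through trend fits, Pearson
    correlation screening and standardised principal component analysis. A
    stochastic daily weather generator with genotype-specific phenology and
    quality responses provides fully synthetic, reproducible test data for a
    Mediterranean dry-summer (Csa) regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
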