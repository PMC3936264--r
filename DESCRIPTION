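Package: crowdcongruence
Title: Congruence of Crowdsourced Hospital Quality Information with Official Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how well hospital-quality beliefs crowdsourced
    from geospecific online health communities agree with official government
    quality data, and for explaining regional variation in that agreement.
    Provides a synthetic corpus generator with known ground truth (hospital
    registries, alias dictionaries with acronyms/abbreviations/misspellings,
    district demographics, and message streams), dictionary-based hospital-name
    extraction with stepwise edit-distance normalization, per-district crowd
    versus government rank alignment, first-principles Kendall tau (tau-a and
    tau-b) and Spearman rho congruence statistics, sociodemographic covariate
    construction, and an ordinary least squares analysis of congruence with raw
    and standardized coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    Rcpp,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
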