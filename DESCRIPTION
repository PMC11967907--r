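Package: stillbirthtrends
Title: Trend Testing and Kitagawa Decomposition of Stillbirth Rates from
    Stratified Birth Registry Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for national stillbirth-rate surveillance from aggregated
    birth-registry counts stratified by maternal age or multiplicity. Reads,
    validates and repairs stratified count tables (proportional redistribution
    of unknown strata, seeded imputation of disclosure-suppressed cells),
    computes stillbirth rates per 1000 total births, tests monotonic trends
    with the Mann-Kendall test under a Hamed-Rao autocorrelation correction,
    estimates annual change via linear or continuous broken-line (segmented)
    regression with a Davies-type score test for a slope change, flags
    anomalous years by robust standardized residuals from a Theil-Sen fit,
    and splits rate differences over time or against a pooled multi-country
    reference into composition and rate components with the Kitagawa
    decomposition. Includes a synthetic registry generator with known ground
    truth and a reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
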