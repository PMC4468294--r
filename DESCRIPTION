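Package: pitscan
Title: Quantification of Osteoclast Resorption Pits from Stylus Profilometry Traces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of one-dimensional stylus profilometry traces of
    resorbed bone discs. Estimates the unresorbed-surface baseline of each
    trace, segments sub-surface erosions into resorption pits, counts the
    dents within each pit to classify it as unidented, bidented or
    multidented, and measures pit width, maximum depth, full-width at half
    maximum and sub-surface cross-sectional erosion area. Pits are
    aggregated to per-subject medians and shape distributions, and cohorts
    are compared with nonparametric tests (Mann-Whitney U, Kruskal-Wallis,
    chi-square). A calibrated synthetic-surface generator emulates Dektak
    scans of osteoclast cultures from Charcot, diabetic and control
    subjects under RANKL and RANKL plus anti-TNF treatment, with planar
    resorption masks and full ground truth, so the whole pipeline can be
    validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
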