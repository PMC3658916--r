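Package: lfdrenrich
Title: Local False Discovery Rate Estimators for Category Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of the local false discovery rate (LFDR) for
    category-enrichment testing of 2x2 tables, built on the conditional
    (nuisance-eliminated) likelihood of the noncentral hypergeometric family.
    Implements the binomial-based estimator (BBE), histogram-based estimators
    with theoretical and empirical nulls (HBE, HBE-EN), type-II maximum
    likelihood over k-component parametric mixtures of conditional pmfs
    (MLE2, MLE3), and a normalized-maximum-likelihood estimator (NMLE)
    that approximates the Bayes factor by the NML ratio. Includes a
    synthetic-data generator for enrichment tables with specified log odds
    ratios, an exact true-LFDR oracle, and a bias-benchmarking harness
    comparing all estimators.
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
    rlang,
    stats,
    splines,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
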