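Package: epifounder
Title: Founder Stem-Cell Estimation from Allele-Specific Methylation and
    X-Inactivation Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allele-specific epigenetic mosaicism from
    methylation-sensitive restriction assays and estimates the number of
    founder (trophoblast stem) cells that gave rise to a tissue from the
    variance of allelic score distributions, using the binomial variance
    relation Var = p(1-p)/N. Provides maternal/paternal methylation ratio
    and X-inactivation skew scores, a moment and a distribution-fit founder
    estimator, group comparison statistics (rank-sum location tests,
    variance-equality tests, delta-delta-Ct fold changes), a loss-of-imprinting
    classifier, and a seeded synthetic-cohort generator that emulates clonal
    mosaicism in placental tissue, so every stage of the analysis can be
    exercised without access to raw densitometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
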