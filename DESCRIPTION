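Package: seedscreen
Title: Seed-Effect Modeling and Cleaning for Pooled shRNA Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and correcting seed-mediated off-target
    effects in genome-wide pooled shRNA loss-of-function screens. Groups
    shRNAs into seed families (guide-strand positions 2-8), computes seed
    essentiality scores and position-shifted heptamer controls, summarizes
    shRNA scores to gene level (GARP and a Kolmogorov-Smirnov enrichment
    variant of RIGER), classifies seeds by seed pairing stability and
    target-site abundance to remove high off-target-propensity constructs,
    measures between-screen reproducibility with rank correlations, and
    detects genetic-interaction and synthetic-lethal partners of driver
    genes. Includes a fully specified two-screen simulator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
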