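Package: aromakit
Title: GC-MS Aroma Metabolomics: Retention Indices, Semi-Quantification,
    Odor Activity Values and Chemometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing integrated HS-SPME-GC-MS peak tables from
    fermented-beverage aroma profiling: van den Dool-Kratz retention-index
    calibration against n-alkane ladders, retention-index based peak
    annotation, internal-standard semi-quantification, chemical-class
    summaries, relative odor activity value (ROAV) scoring with key-odorant
    selection, and a chemometrics layer (probabilistic quotient
    normalization, Pareto scaling, Spearman correlation, principal
    coordinate analysis, NIPALS PLS-DA and OPLS-DA with VIP scores,
    stratified cross-validation and permutation testing). Ships a
    transcribed nine-wine reference panel of 128 volatile compounds with
    odor thresholds, and a seeded synthetic-panel generator with known
    ground truth for end-to-end testing of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
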