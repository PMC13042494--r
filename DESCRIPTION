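Package: cscore
Title: Concordance Scoring of Paired Differential-Expression Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whether genes or pathways respond the same way or
    differently in two case-versus-control comparisons using a continuous
    concordance statistic (the C-score), with a cross-pairing permutation
    significance test and shared/different pattern classification. Builds
    C-score-weighted directional ligand-receptor cell-cell communication
    networks across cell types with in-/out-degree and sender/receiver gene
    rankings. Includes exact small-sample statistics (one-sided hypergeometric
    overlap, exact Mann-Whitney U), a synthetic dual-contrast generator with
    planted ground truth for benchmarking, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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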