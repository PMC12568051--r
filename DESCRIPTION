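Package: gablup
Title: Genomic Prediction with GWAS-Prior-Weighted Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic selection for repeated-record quantitative traits using
    additive and dominance genomic relationship matrices with a trait-specific
    weighting of GWAS-prioritised markers (GBLUP-GA). Provides genotype
    simulation and input/output with quality control, a minimal
    additive-plus-dominance single-SNP association scan, VanRaden-style
    additive and heterozygosity-based dominance relationship matrices,
    average-information REML for the repeated-record animal model with
    permanent environment effects, the prior-variance-share weight tau and
    the weighted relationship matrix, and five-fold cross-validated
    prediction accuracy with scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
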