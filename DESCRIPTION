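Package: stratomir
Title: Ancestry- and Obesity-Stratified miRNA-mRNA Integration for
    Tumor Expression Studies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative small-RNA / mRNA analysis pipeline for paired
    tumor and adjacent-normal expression studies stratified by ancestry and
    body-mass-index class, modeled on triple-negative breast cancer cohorts.
    Provides count filtering, trimmed-mean-of-M-values (TMM) normalization,
    a negative-binomial Wald differential-expression engine with
    Benjamini-Hochberg correction, a multistep set-subtraction strategy that
    isolates obesity-exclusive, ancestry-specific miRNA signatures, a
    target-prediction-restricted Spearman correlation network with
    direct/indirect regulation classification, hypergeometric gene-set
    enrichment, a two-cluster separation check, and a synthetic study
    generator that plants known differential expression and miRNA-target
    repression so every stage can be scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
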