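Package: scduet
Title: Same-Cell Transcriptome and Metabolome Analysis for Plant Protoplasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for plate-based single-cell experiments in
    which each protoplast lysate is split between targeted LC-MS metabolomics
    and SMART-seq style transcriptomics. Provides targeted absolute
    quantification from external calibration curves (limit of quantification,
    split-lysate doubling, spherical cell-volume normalization), single-cell
    RNA quality control, TPM and log-normalization, variance-stabilized
    variable-gene selection, well-identity integration of the two modalities,
    rule-based dual (RNA- and metabolite-guided) cell-type annotation with
    cross-tabulation, gene-metabolite Spearman correlation and rank curves,
    local-regression expression-concentration trends, transporter-metabolite
    bipartite networks, and subcluster Wilcoxon differential expression. A
    fully specified synthetic-plate generator with known ground truth makes
    every stage testable without external data.
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
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
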