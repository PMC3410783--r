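Package: oxymir
Title: Integrated miRNA-mRNA Expression Analysis for Hyperoxia-Induced Lung Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of an integrated microRNA-mRNA
    expression analysis pipeline for the neonatal hyperoxia model of
    bronchopulmonary dysplasia. Provides TaqMan low-density-array CT
    processing (ceiling rule, U6 delta-CT normalisation, absolute copy-number
    quantification), quantile normalisation and low-expression filtering of
    log2 expression matrices, per-contrast differential expression via a
    pooled-variance cell-means model with Benjamini-Hochberg FDR control and
    derived raw-p cutoffs, cross-contrast expression-pattern classification,
    anti-correlation x predicted-target miRNA-mRNA pairing with cross-database
    overlap, hypergeometric gene-set enrichment with a two-list comparison,
    qPCR relative and standard-curve quantification, and a synthetic
    data generator with planted ground truth that makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
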