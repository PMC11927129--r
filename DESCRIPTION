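Package: gwablup
Title: Multitrait Genomic Prediction with GWAS-Weighted SNP-BLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multitrait genomic prediction in which genome-wide association
    results re-weight the prior (co)variance of every SNP inside a multitrait
    SNP-BLUP mixed model (GWABLUP). Correlated traits are canonically
    transformed to genetically and environmentally independent traits, scanned
    SNP by SNP, and the resulting likelihood ratios are smoothed along the
    genome and converted to posterior probabilities of non-zero SNP effects.
    These act as SNP weights - uniform across traits or trait specific - when
    assembling per-SNP prior covariance blocks for the augmented mixed-model
    equations, which are solved matrix-free by a preconditioned conjugate
    gradient with a block-diagonal preconditioner. Includes validation tools
    (reliability, inflation slope, bootstrap method comparison) and a
    synthetic-data generator with sparse, partially overlapping QTL
    architectures for method evaluation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
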