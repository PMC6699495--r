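Package: crosstrait
Title: Transcriptome-Wide Association and Cross-Trait Genetic
    Correlation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An integrative summary-statistics toolkit for studying the
    shared genetic basis of complex traits.  Implements a
    transcriptome-wide association scan (expression-weight by GWAS
    Z-score statistics under reference linkage disequilibrium), LD score
    regression estimates of SNP-heritability and cross-trait genetic
    correlation with block-jackknife standard errors, local
    SNP-heritability and local genetic correlation in approximately
    independent LD blocks via truncated quadratic forms, and a
    putative-causality contrast that compares summed local correlations
    over trait-specific risk regions.  A synthetic-data generator
    produces LD blocks, two-trait genetic architectures, GWAS summary
    statistics and sparse cis-eQTL weight models with the statistical
    structure the analyses assume, so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
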