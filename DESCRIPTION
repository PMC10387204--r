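Package: gwsub
Title: GWAS-by-Subtraction for Parental-Phenotype Summary Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives genome-wide association study (GWAS) summary statistics
    for a parental phenotype from an index-person GWAS and the other parent's
    GWAS using a weighted linear model (GWAS-by-subtraction), with standard
    error propagation. Includes unit rescaling onto the standardised mean
    difference scale, quality-control diagnostics (genomic inflation factor,
    Manhattan and QQ plots), a Monte-Carlo simulation framework for validating
    the estimator on trio-structured data, a two-sample Mendelian
    randomization validation stage (instrument selection, winner's-curse
    correction by FDR inverse quantile transformation, LD clumping, allele
    harmonization, inverse-variance-weighted estimation with multiplicative
    random effects), and generators for synthetic trio genotype and
    summary-statistic data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
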