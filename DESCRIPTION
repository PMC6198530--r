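Package: methslope
Title: Between-Individual Variation in the Rate of Longitudinal DNA
    Methylation Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis of DNA methylation trajectories in
    repeated-measures cohorts. Fits, per CpG probe, a linear mixed model
    with a per-individual random intercept and random slope on
    standardized age, and tests the random-slope variance component with
    a boundary-corrected likelihood-ratio test whose null distribution is
    the 50:50 mixture of a point mass at zero and chi-squared with one
    degree of freedom. Provides preprocessing (M-value transformation and
    clamping, outlier removal, batch and covariate residualization,
    genotype quality control), genome-wide probe scans with two-group
    replication, permutation calibration of the test statistic, bootstrap
    confidence intervals for between-group correlations, GWAS of SNP
    dosages on predicted (BLUP) random slopes with LD clumping and
    cis/trans classification, annotation and gene-set enrichment tests,
    and a simulation study comparing strategies for detecting SNP-by-age
    interaction effects on methylation. Includes a synthetic-cohort
    generator so that every stage of the pipeline can be exercised and
    calibrated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomeInfoDb,
    BiocGenerics,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
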