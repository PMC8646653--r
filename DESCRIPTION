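Package: pathprs
Title: Pathway-Stratified Polygenic Risk Scores and Cross-Trait Genetic
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for testing epidemiological and genetic
    association between an ordinal, age-dependent trait (male androgenetic
    alopecia, self-reported on a four-level pattern scale) and a binary
    disease outcome (hospitalization with COVID-19). Implements age-corrected
    two-stage regression, LD score regression for heritability and cross-trait
    genetic correlation with block-jackknife standard errors, genome-wide
    polygenic risk scoring with p-value thresholding and LD clumping, and
    pathway-restricted polygenic risk scores built by positional SNP-to-gene
    mapping against gene-set libraries, with Benjamini-Hochberg false
    discovery rate control per analysis iteration. A synthetic-cohort module
    simulates LD-blocked genotypes, liability-threshold ordinal phenotypes,
    logistic disease outcomes with an optional pathway-confined shared genetic
    component, and model-consistent GWAS summary statistics, so every stage is
    testable against known ground truth without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    vcfR,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
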