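Package: mbdDMR
Title: Methylation Estimation from MBD-Enrichment Arrays and
    Phenotype-Associated DMR Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates absolute DNA methylation from MBD-enrichment
    promoter-array signal with CpG-density coupling, calls
    phenotype-associated differentially methylated regions (DMRs) by
    robust window regression and Fisher-exact span enrichment, reduces
    correlated CpGs to representative test variables by contiguous
    clustering and median-absolute-deviation ranking, handles cellular
    heterogeneity via reference-free surrogate variables, reference-based
    cell proportions and a variance-inflation collinearity guard, and fits
    covariate-adjusted methylation-adiposity and methylation-expression
    association models. Ships a synthetic-data generator emulating
    mother-offspring cohort studies so the whole pipeline is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
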