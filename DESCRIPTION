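Package: gebvtrend
Title: Genomic Prediction and Drift Nulls for Microevolutionary Trend Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects microevolutionary change of a quantitative trait in a
    pedigreed, genotyped wild population. Implements a two-stage genomic
    prediction workflow (repeatability mixed model for phenotype adjustment,
    then a BayesR-style four-component normal-mixture Gibbs sampler for SNP
    effects and posterior genomic breeding values), a Bayesian pedigree animal
    model with a sparse numerator-relationship-matrix inverse, posterior-aware
    weighted regression of cohort mean breeding values on birth year, and two
    explicit drift nulls: gene-dropping of phased haplotypes through the
    pedigree with recombination, and midparent breeding-value dropping. A
    forward simulator generates overlapping-generation pedigrees, LD-structured
    haplotypes and phenotypes with a cryptic-evolution regime so the whole
    pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
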