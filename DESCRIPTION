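Package: ordgwas
Title: GWAS, Meta-Analysis, Fine-Mapping and Selection Scans for Ordinal Traits
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for genome-wide association studies of
    ordinal (rater-scored) traits across multiple cohorts: genotype quality
    control, LD pruning and PCA covariates, additive and conditional linear
    association scans with genomic-control diagnostics, fixed- and
    random-effects meta-analysis with Cochran's Q and I-squared
    heterogeneity, approximate-Bayes-factor credible-set fine-mapping, and
    three families of positive-selection tests: haplotype-based iHS scans,
    pairwise log-odds selection-difference tests, and a polygenic-score
    divergence (Qx-style) test against a drift null built from
    frequency-matched neutral variants. A forward Wright-Fisher simulator
    with selection, recombination and population splits, plus an ordinal
    genotype-to-phenotype generator with multi-rater scoring noise, provides
    truth-tagged synthetic cohorts for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
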