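Package: gbcpred
Title: Genomic Prediction Combining G-BLUP and Bayes-C Components
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-genome regression tools for genomic prediction in
    progeny-tested livestock populations. Implements genomic best linear
    unbiased prediction (G-BLUP) with a VanRaden method-1 genomic
    relationship matrix, a spike-and-slab Bayes-C Gibbs sampler, and the
    GBC method: a fast iterative conditional expectation (ICE) fit of a
    Bayes-C large-effect SNP term simultaneously with a G-BLUP polygenic
    term, including a prediction-error-variance correction to the SNP
    likelihood ratio. Ships an evaluation toolkit (daughter-yield-deviation
    reliability, accuracy, bias, bootstrap standard errors,
    Hotelling-Williams test for dependent correlations), a half-sib
    genotype/phenotype simulator, file readers and writers for delimited
    and PLINK RAW genotype formats, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
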