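Package: adipoflux
Title: Stable Isotope Tracing and 13C Metabolic Flux Analysis for Adipocyte
    Central Carbon Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computation stack for GC-MS stable-isotope tracer studies of
    cultured adipocytes: natural-abundance correction of mass isotopomer
    distributions (MIDs), mole percent enrichment, extracellular exchange
    rates, steady-state 13C label simulation via the elementary metabolite
    unit (EMU) framework on an atom-mapped compartmentalized network of
    glycolysis, the TCA cycle, branched-chain amino acid oxidation and fatty
    acid synthesis, nonlinear least-squares flux estimation with chi-squared
    goodness-of-fit and profile-likelihood confidence intervals, isotopomer
    spectral analysis (ISA) of de novo lipogenesis, and a ground-truth
    synthetic data generator for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    boot,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
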