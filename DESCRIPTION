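Package: mixedclust
Title: Model-Based Co-Clustering of Mixed Binary and Continuous Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint model-based clustering of entities described by mixed
    binary and continuous variables (e.g. transcription-factor binding plus
    gene expression, or somatic mutations plus tumour expression profiles)
    using a finite mixture of independent Bernoulli and diagonal Gaussian
    components. The number of clusters and the assignment of entities are
    found by minimising a penalised-likelihood objective (AIC-type constant
    penalties, BIC, Hannan-Quinn, consistent AIC) with Monte-Carlo simulated
    annealing, followed by expectation-maximisation refinement under the full
    mixture likelihood. Includes a synthetic-data generator for calibration
    studies, variable-preselection and filtering utilities for binding and
    mutation data, "clear cluster" reporting, regulatory network edge export,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mclust,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
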