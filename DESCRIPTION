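Package: cornas
Title: Coverage-Dependent Differential Gene Expression for Unreplicated RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls differentially expressed genes between two unreplicated
    RNA-Seq samples by comparing Bayesian posterior distributions of true
    gene counts. The observed count given a true count is modelled with a
    Generalized Poisson distribution whose dispersion is governed by the
    sequencing coverage, the fraction of the cDNA fragment population that
    was sequenced. Coverage is estimated from sequencing depth, RNA loading
    concentration and PCR amplification arithmetic, so no between-sample
    normalization and no transcript length information are needed. Includes
    the hypergeometric fragment-sampling simulator that motivates the count
    model, confusion-matrix and ROC utilities for benchmarking callers, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
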