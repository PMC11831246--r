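Package: protomix
Title: Prototype, Exemplar and Mixture Models for Dot-Pattern Category
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying single-category dot-pattern learning with
    prototype, exemplar and mixture observation models. Generates
    Posner-style 9-dot stimulus sets under configurable distance
    constraints, simulates cohorts of agents whose strategy mixture,
    sensitivity and decision criterion evolve over training, fits all
    model variants per subject by Markov chain Monte Carlo under uniform
    priors with a two-stage initialization protocol, and compares models
    by the deviance information criterion. Includes convergence
    diagnostics, participant-level quality-control filters, parameter-
    and model-recovery experiments, and similarity-vector export for
    downstream trial-wise analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    rjags,
    coda,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
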