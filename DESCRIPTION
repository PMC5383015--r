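Package: grnevolve
Title: Evolution of Generalising Developmental Organisation in Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the evolution of a recurrent gene-regulatory-network
    (GRN) developmental map under switching selective environments drawn from
    a modular phenotype class, and analyses when the evolved developmental
    organisation generalises beyond the environments it was selected in.
    Provides a strong-selection/weak-mutation hill climber with
    benefit-minus-cost fitness (L1/L2 connection costs, environmental noise),
    Classify-and-Count estimation of induced phenotype distributions from
    scrambled Sobol samples of embryonic states, chi-squared training/test
    error and entropy traces, lambda/kappa sensitivity sweeps, and a
    rate-of-adaptation assay with frozen regulatory interactions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
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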