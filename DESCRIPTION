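Package: mutfidelity
Title: Mutation-Rate Estimation, Replication-Fidelity Arithmetic, and
    Error-Induced Extinction Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying DNA replication fidelity in
    microbial reporter-gene assays. Estimates mutation rates from
    Luria-Delbrueck fluctuation assays by maximum likelihood under the
    Lea-Coulson model (Ma-Sandri-Sarkar recursion) with likelihood-ratio
    confidence intervals and support for diluted platings via binomial
    thinning. Classifies mutations against a coding reference, tallies
    mutation spectra, and converts phenotypic rates to per-base-pair
    rates with Drake-style corrections for undetectable (silent)
    substitutions. Computes repair-pathway efficiencies from fold
    effects, predicts double-mutant rates, grades growth capacity, and
    simulates error-induced extinction of colonies as a Galton-Watson
    branching process with an analytic oracle. Includes seeded
    generators of synthetic fluctuation-assay counts and mutant
    spectra so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
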