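Package: amortHMM
Title: Amortized-Emission Hidden Markov Models for Nanopore 5mC Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gaussian-emission hidden Markov model calling of 5-methylcytosine
    (5mC) at CpG sites from aligned nanopore current events, for the setting
    where the training data do not cover all possible methylated k-mer
    contexts.  Emission distributions missing from training are imputed by a
    small feedforward network mapping a binary k-mer featurization to Gaussian
    parameters, trained with a symmetrized Kullback-Leibler loss.  Includes an
    exact integer-program based coherent k-mer panel designer (whole methylated
    11-mers are selected together, as a real sequencing experiment would
    produce), a synthetic nanopore signal simulator, and an evaluation harness
    that decomposes calling error into sensor and k-mer generalization and
    low/high k-mer novelty.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
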