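Package: biophyslm
Title: Biophysics-Pretrained Protein Language Models for Variant Effect
    Prediction and Sequence Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pretrains small transformer encoders on simulated biophysical
    score terms of protein variants and transfers them to experimental
    sequence-function data. Provides structure-based (contact-graph) and
    sequence-based relative position embeddings, a seeded synthetic
    biophysics simulator with known additive-plus-epistatic ground truth,
    robust preprocessing of simulated score tables, replicated small-sample
    and extrapolation benchmark splits, epistasis scoring, and simulated
    annealing sequence design with clustering-based candidate selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    igraph,
    bio3d,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
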