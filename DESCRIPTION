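Package: genarch
Title: Neural Architecture Search for Genomic Sequence Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatically designing convolutional and recurrent
    neural networks for DNA sequence classification. Provides a
    genomics-specific hyperparameter search space, a deterministic builder
    that expands a hyperparameter configuration into a three-stage
    architecture plan (stacked convolutional blocks, a global-average-pooling
    or recurrent embedding stage, and a fully connected stage), a
    Gaussian-process model-based optimizer with batch upper-confidence-bound
    proposals and multi-fidelity warm starts, a class-balanced FASTA
    streaming pipeline, a budgeted training harness with plateau-based
    learning-rate scheduling and early stopping, and a planted-motif
    synthetic genome generator so the whole loop runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
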