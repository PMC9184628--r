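Package: hostsieve
Title: Reference-Free Host Read Depletion with a Length-Flexible
    Convolutional Classifier
Version: 0.1.0
Authors@R:
    person("hostsieve", "developers", email = "hostsieve@example.org",
           role = c("aut", "cre"))
Description: Separates host from microbial long reads without any reference
    database or alignment index.  A small convolutional neural network with
    global average pooling scores each read with a host probability at its
    native length; reads are grouped into length bins, truncated to the bin
    boundary, batched under a memory budget, and labelled through
    length-dependent probability thresholds.  The package also provides the
    training and threshold-calibration procedures, a DeepLift-style
    reference-based attribution method aggregated to 15-mers, evaluation
    utilities (sensitivity/specificity, CG-dinucleotide baselines and
    stratification, k-mer uniqueness), and a Markov-chain synthetic read
    generator that emulates vertebrate CG suppression so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
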