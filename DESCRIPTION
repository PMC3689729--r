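Package: boolinfer
Title: Inference of Boolean Networks from Time-Series Data
Version: 0.1.0
Authors@R: person("Boolinfer", "Developers", email = "boolinfer@example.org",
    role = c("aut", "cre"))
Description: A two-stage framework for reverse engineering Boolean gene
    regulatory networks from real-valued time-series concentration data.
    Stage one discretizes each species' trajectory into a binary profile
    (two-cluster k-means, iterative k-means, or BASC A step-function
    binarization) and removes false steady-state redundancy.  Stage two
    learns Boolean update rules from the binary trajectories with REVEAL
    (mutual information), Best-Fit extension of partially defined Boolean
    functions, or Full-Fit enumeration.  Learned networks can be simulated
    synchronously or asynchronously (SSA-style single-gene updates averaged
    over runs), scored against the binarized data with a normalized Hamming
    trajectory error, searched for minimum-error models, and validated by
    leave-one-out cross-validation of one-step predictive power.  A
    synthetic-data module integrates a four-gene oscillatory toy regulatory
    network so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
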