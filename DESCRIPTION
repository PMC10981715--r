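Package: finaleme
Title: Predict DNA Methylation of Cell-Free DNA from Fragmentation Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the FinaleMe model: a non-homogeneous two-state hidden
    Markov model that predicts the methylation status of every CpG on every
    plasma cell-free-DNA fragment directly from whole-genome-sequencing
    fragmentation features (fragment length, normalized coverage, and the
    distance of each CpG to the fragment center). Per-fragment calls are
    aggregated into continuous per-CpG methylation tracks, evaluated against
    ground truth, and used to estimate tissue-of-origin fractions by
    constrained quadratic programming against a reference methylome panel.
    Includes a fully synthetic data generator (toy genome, cell-type
    methylomes, state-coupled cfDNA fragments) so the whole pipeline is
    testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    quadprog,
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
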