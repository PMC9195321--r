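Package: corread
Title: Context-Aware Error Correction of Illumina Short Reads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-sequence-alignment based correction of substitution
    errors in Illumina short reads. Candidate reads are retrieved per anchor
    read with a minhash index over canonical k-mers, aligned by gapless
    shifted Hamming distance, filtered (optionally using paired-end mate
    information), and stacked into a weighted anchor-centered alignment whose
    consensus drives per-base correction. Low-confidence positions can be
    vetted by random-forest classifiers trained on simulated reads with a
    leave-one-genome-out protocol. Includes a paired-end read simulator with
    an error-free twin output, per-base true/false-positive evaluation
    against the twin, and lost-true-k-mer spectrum analysis against a
    reference genome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
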