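Package: chromconverge
Title: Convergence Analysis of Chromatin Regulator Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for testing whether two chromatin
    regulators converge on shared genomic targets and transcriptional
    programs. Implements replicate-concordance filtering of ChIP-seq peak
    calls, promoter/TSS annotation with random-position fold enrichment and
    TSS metaprofiles, a minimal negative-binomial two-group differential
    expression stage with background filtering, hypergeometric gene-set
    overlap statistics with direct/indirect/hub target classification,
    courtship-conditioning learning-index statistics with a bootstrap
    randomization test, and delta-delta-Ct / percent-input qPCR arithmetic.
    A synthetic-data module generates genomes, peak replicates, count
    matrices and courtship tables with known ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
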