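Package: rexscan
Title: Motif Scanning and ChIP Signal Analysis for Nematode Dosage
    Compensation Recruitment Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing DNA sequence motifs that recruit the
    nematode dosage compensation complex (DCC) to X chromosomes.
    Implements Patser-style position weight matrix scoring with exact
    ln(P) p-values from a dynamic-programming score distribution,
    chromosome-wide motif scanning on both strands, cumulative
    X:autosome motif-density enrichment curves, RPKM normalisation and
    simple occupancy peak calling for ChIP-seq coverage, motif-anchored
    meta-profiles, rex-site annotation with inter-motif spacing,
    ChIP-qPCR standard-curve quantification and control-site
    normalisation, viability and XO-rescue percentage formulas, tryptic
    peptide mass fingerprinting with monoisotopic MH+ calculation and
    ppm matching, and a synthetic-data generator that emulates the
    X-versus-autosome structure of the analysis so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
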