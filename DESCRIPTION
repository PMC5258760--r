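Package: mirqtl
Title: Integrating Small-RNA Differential Expression with Substitution-Line
    QTL Mapping for Rice Heat Tolerance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for nominating candidate miRNAs and
    target genes underlying heat tolerance at the rice flowering stage.
    Calls differentially expressed miRNAs from pooled small-RNA count
    libraries (TPM normalisation, Fisher's exact test, Benjamini-Hochberg
    FDR), phenotypes heat tolerance from spikelet counts (spikelet fertility
    and the heat tolerance index), maps QTLs from a panel of chromosome
    single-segment substitution lines (graphical-genotype segment lengths,
    per-line t-tests, additive effects), scores plant-style miRNA-target
    complementarity with seed-weighted penalties, and intersects target-gene
    coordinates with QTL intervals to rank anti-correlated candidate pairs.
    A synthetic-data module generates every input the pipeline reads, with
    planted effects, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
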