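Package: moaseq
Title: MNase Footprint Profiling, Segmentation and Simulation for
    Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for MNase-defined occupancy analysis of chromatin:
    ingestion and deduplication of aligned paired-end fragments, binned
    coverage and fragment-midpoint ("frenter") footprint tracks,
    biological-cutoff segmentation with genomic-fraction calibration,
    reproducibility and enrichment quality metrics, metagene, metapeak and
    expression-quintile aggregation, IUPAC oligo and dyad motif scanning
    with enrichment folds and per-motif catalogs, and a synthetic
    chromatin digestion simulator with ground-truth evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
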