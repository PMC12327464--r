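Package: scmtr
Title: Simulation and Processing of Multi-Target Single-Cell CUT&Tag with
    Transcriptome (scMTR-seq) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for multi-target single-cell CUT&Tag with joint
    transcriptome readout (scMTR-seq). Models the three-round split-pool
    combinatorial barcode architecture (capacity, collision rates, whitelist
    Hamming distances), simulates ground-truthed paired-end reads with the
    assay's fixed Read2 layout, demultiplexes reads into (cell, modality,
    target) assignments with optional one-mismatch whitelist correction,
    provides a desk-scale exact aligner and a minimal SAM reader, performs
    modality-specific deduplication into fragment files and a gene-by-cell
    UMI count matrix, and computes the assay's quality-control and
    association statistics: FRiP, duplication rates, cell filtering and
    recovery, Cramer's V between binarized modalities, k-nearest-neighbor
    label agreement, IgG-normalized pseudobulk tracks, binned track
    correlations, subsampling saturation curves, median depth
    normalization, and Poisson-threshold binarization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
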