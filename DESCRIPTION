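Package: dimerspec
Title: Dissecting Transcription-Factor Dimer Binding Specificity from
    DAP-Seq and Double DAP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of DNA affinity purification sequencing
    (DAP-seq) and double DAP-seq experiments that contrast transcription
    factor heterodimer and homodimer DNA binding. Implements control-based
    blacklist construction, consensus peak building, genome-wide binding
    correlation and clustering, a simplified between-sample normalization
    and moderated differential-binding test, k-mer motif-category scanning
    with half-site exclusion rules and Fisher enrichment, closest-gene
    target scoring, and an exact minimal hypergeometric (mHG) test for
    ranked gene-set association. A seeded synthetic-data module generates
    genomes, peaks, replicate count matrices, control samples and gene
    sets with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    ape,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
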