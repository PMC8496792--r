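Package: ribodesign
Title: Anti-rRNA Oligonucleotide Probe Design for RNase H-Based rRNA
    Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Designs tiled anti-rRNA oligonucleotide probes (ArOPs) for
    enzymatic ribosomal RNA depletion in bacterial transcriptomics.
    Builds per-type rRNA consensus templates from annotated genomes,
    places reverse-complementary probes under a melting-temperature
    threshold with a maximum-gap tiling rule, derives pre-rRNA operon
    regions (leaders, spacers, trailers) for supplementary probes,
    evaluates probe sets for coverage gaps, cross-species transfer and
    off-target consecutive matches, and computes the rRNA-fraction
    read-accounting used to quality-control depletion experiments.
    Includes a deterministic synthetic-data generator for annotated
    rRNA-operon genomes, diverged rRNAs and classified read sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
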