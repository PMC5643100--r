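Package: chromarc
Title: Regulatory Chromatin Architecture Analysis from Accessibility,
    Histone-Mark and Chromatin-Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for regulatory chromatin studies built around
    ATAC-seq accessibility: sliding-window peak calling, replicate-aware
    negative-binomial differential accessibility with BH-FDR control,
    centered-correlation k-means clustering of tag-density profiles around
    peak centers, enhancer taxonomy (poised/active/super-enhancer via a
    rank-curve tangent cutoff) with observed/expected genomic-element
    enrichment, nucleosome dyad-spacing estimation around transcription-factor
    motifs from mononucleosome-sized paired-end fragments, ChIA-PET-style
    pairwise interaction enrichment against a feature-randomization null, and
    a co-regulated-site intersection cascade. A synthetic-data module
    generates peak count tables, fragment-length mixtures with planted
    flanking-nucleosome dyads, histone-mark region sets and feature-anchored
    interactions with unique molecular identifiers, so the full pipeline is
    testable end to end without sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
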