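Package: ncRNAcurator
Title: Curated Genome-Wide Annotation of Plant Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to curate genome-wide non-coding RNA annotations in plant
    genomes from heterogeneous evidence. Merges similarity, covariance-model
    and specialist search hits with strand-aware overlap resolution and a
    coverage/identity/e-value/bit-score tie-break cascade; applies
    class-specific filters for spliceosomal U snRNAs, tRNAs (with
    selenocysteine false-positive flagging and isoacceptor accounting) and
    rRNA unit labelling; validates snoRNAs by C/D and H/ACA box motifs and
    calls genomic snoRNA clusters; curates miRNA precursors against plant
    annotation criteria (hairpin folding by base-pair maximisation, mature
    duplex geometry, expression support) and scores miRNA targets with an
    expectation penalty; identifies and positionally classifies long
    non-coding RNAs against gene models; flags expression evidence from
    small-RNA libraries; and builds neighbor-joining trees from p-distances
    with bootstrap support. A seeded synthetic-data generator plants ground
    truth loci of all six classes so that every stage is testable end to end.
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
    ape,
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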