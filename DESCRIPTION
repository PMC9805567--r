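Package: condseg
Title: Genome Segmentation and Putative Transcriptional Condensate Calling
    from Multi-Omics Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments the genome from multiple one-dimensional omics
    coverage tracks (ChIP-seq, ATAC-seq) by reducing a binned signal
    matrix to its first principal component and detecting structural
    breakpoints with a sliding-window least-squares changepoint model.
    Segments are annotated as enhancer-enriched or enhancer-depleted
    against a permutation background fitted with a zero-inflated
    negative binomial distribution, and normalized chromatin-contact
    scores are pooled per segment pair to call putative transcriptional
    condensates (PTCs) as connected components of strongly interacting
    enhancer-enriched segments. Includes a seeded synthetic-fixture
    generator with planted segment structure and 3D hubs for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    data.table,
    igraph,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
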