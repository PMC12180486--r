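Package: ctxsearch
Title: Context-Aware Protein Embedding Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An embedding-based protein similarity search engine that is
    aware of genomic context. Proteins and their gene neighborhoods are
    mapped to unit vectors by a pluggable embedder, optionally reshaped by a
    contrastively trained linear projection (InfoNCE over in-batch
    negatives), and indexed with a from-scratch hierarchical navigable small
    world (HNSW) graph for approximate nearest-neighbor search under cosine
    similarity. Includes FASTA/GFF3 ingestion with gene-neighborhood
    extraction, greedy identity-threshold sequence clustering for database
    deduplication, Needleman-Wunsch and Smith-Waterman alignment with
    identity and coverage statistics, density-based clustering of retrieved
    context proteins to rank co-occurring genes, annotation transfer via a
    CLIP-style cross-modal aligner, retrieval benchmarks (sequence, genomic
    context, structural family, paired homolog, out-of-distribution), and
    synthetic data generators for offline evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
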