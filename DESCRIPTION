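Package: covnet
Title: Similarity Networks and Recommendations for Genomic Coverage Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns genome-wide read coverage tracks (bigWig or bedGraph) into
    transcripts-per-million profiles over fixed genomic feature sets, compares
    datasets categorically by ontology-annotated metadata (shared key parent
    classes, with an interaction-evidence requirement for transcription-factor
    target pairs) and by primary data (random-forest feature filtering followed
    by multi-layer-perceptron prediction of key ontology classes), assembles the
    pairwise verdicts into a collapsed similarity network with force-directed,
    dendrogram and PCA views, and generates per-user dataset recommendations
    from ownership, favorites and follows while respecting public/private
    visibility. Ships seed-reproducible synthetic cohort, ontology, interaction
    and coverage-track generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    GenomeInfoDb,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
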