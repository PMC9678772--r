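Package: chromcoloc
Title: Colocalization and Regulatory-Element Enrichment Analysis for
    Chromatin Interval Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a set of ChIP-seq peaks colocalizes
    with transcription-factor binding catalogs and regulatory chromatin.
    Implements shuffle-based permutation nulls for genomic intervals with
    per-chromosome placement and restricted universes, multi-scale flank
    analysis with Benjamini-Yekutieli adjustment, Fisher-exact feature
    overlap tests, promoter and open-chromatin annotation, enhancer-gene
    pairing of regulatory elements against differential-expression lists,
    dual-background transcription-factor enrichment with per-megabase
    densities, binary presence-matrix PCA with SVD imputation and
    hierarchical clustering, position-weight-matrix motif scanning with
    control-based fold enrichment, and a seeded synthetic-data generator
    that emulates every input with planted, recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
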