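Package: germchrom
Title: Chromatin Profiling Quantification for the Drosophila Male Germline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies chromatin profiling (CUT&Tag-style) fragment data
    over promoter windows, gene bodies, transposon consensus sequences and
    fixed-width genomic bins; derives strand-aware transcription start site
    (TSS) tables from GTF gene models; summarizes testis single-nucleus
    expression atlases into germline/somatic enrichment and k-means
    developmental stages; and computes chromosome-scale dosage-compensation
    statistics with hemizygous per-copy normalization and autosome-median
    scaling. Includes a synthetic-data generator with planted ground truth
    (per-chromosome enrichment factors, expression-coupled Poisson fragment
    rates, staged cluster-expression archetypes) so the full pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
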