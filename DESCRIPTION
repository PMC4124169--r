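Package: lncislet
Title: Alpha- and Beta-Cell Transcriptome Analysis with Novel lncRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, desk-scale pipeline for comparing FACS-purified
    pancreatic alpha- and beta-cell transcriptomes: RPKM quantification against
    an exon model, negative-binomial differential expression with
    median-of-ratios normalization and Benjamini-Hochberg FDR control,
    cross-species (mouse vs human) beta-cell transcriptome classification via
    one-to-one orthologs and a liftOver-style block map, rule-based discovery
    of novel long non-coding RNAs from read-density segmentation, transcription
    factor peak enrichment at transcript ends with permutation p-values,
    position weight matrix scanning with motif-cluster detection, and
    lncRNA/nearest-gene co-regulation statistics. A synthetic-data generator
    plants ground truth for every stage so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
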