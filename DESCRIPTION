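Package: perichrom
Title: H3K9me2 Domain Segmentation and Peripheral Heterochromatin Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of H3K9me2 CUT&RUN coverage: spike-in
    normalization of binned genome tracks, four-state hidden Markov model
    segmentation into background, intermediate-density (class 1),
    high-density (class 2), and artifact (blacklist) states, replicate
    consensus domain calling, domain statistics and cross-condition sharing,
    gene and transposable-element domain assignment, expressed-fraction and
    domain-flow accounting, and per-copy transposon derepression calling.
    Includes a synthetic-data generator that plants domain maps, expression
    effects, and derepressed transposon copies with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
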