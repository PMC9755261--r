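Package: lncregnet
Title: Salt-Responsive lncRNA Discovery and Regulatory Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for identifying long non-coding RNAs
    (lncRNAs) from assembled transcript models and characterising their
    regulatory roles under salt stress. Implements the classic
    class-code/expression/length/coding-potential filtering cascade with
    category assignment (sense, antisense, intronic, lincRNA),
    fold-change based differential-expression calling and 2^-ddCt qPCR
    arithmetic, cis-target inference by genomic windowing plus
    correlation and trans-target inference by simplified co-expression
    module detection with Fisher enrichment, chromatin-accessibility
    significance testing against a random-region null, in-silico
    mutagenesis of regulatory sequence against a pluggable accessibility
    predictor, position-weight-matrix motif scanning with exact
    dynamic-programming p-values, and miRNA target-mimicry scoring by
    banded complementarity alignment. A seeded synthetic-data generator
    with a ground-truth manifest makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
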