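Package: strandcheck
Title: Infer Strandedness of Paired-End RNA-Seq Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines whether a paired-end RNA-seq library is FR-stranded,
    RF-stranded or unstranded without a full alignment step. A sample of read
    pairs (200,000 by default) is assigned to the transcriptome with a
    strand-aware k-mer voting index, each pair is classified into the FR/RF
    orientation space, and the stranded proportion -- the fraction of
    determinable pairs explained by the dominant layout -- is compared against
    decision thresholds (above 0.9 stranded, below 0.6 unstranded) to produce
    a verdict with quality-control warnings. A strand-configurable paired-end
    read simulator (including a genomic-DNA control mode) is included so the
    whole pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
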