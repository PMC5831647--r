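Package: cohesinmeta
Title: Meta-Origin Analysis of Cohesin ChIP-seq, Expression and DNA Fiber Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Input-normalized sliding-window ChIP-seq enrichment, meta-origin
    profile and ratio analysis around early DNA replication origins with
    per-bin Wilcoxon signed-rank tests, percentile-threshold binding-region
    calling with overlap statistics, enrichment at 500 bp regulatory elements
    by class, depletion-versus-mock RNA expression contrasts with Fisher
    overlap tests, and dual-label DNA fiber tract statistics. A seeded
    synthetic-data generator emulates the statistical structure of cohesin
    regulation ChIP-seq, RNA-seq and fiber experiments so the whole pipeline
    runs end to end with ground truth and no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
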