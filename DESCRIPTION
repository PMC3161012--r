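Package: paraconv
Title: Detection and Dating of Ectopic Gene Conversion Between Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical detection of non-allelic (ectopic) gene conversion
    between paralogous sequences in gene clusters, across multiple species.
    Implements the hypergeometric random-walk maximum-descent test on
    paralog/ortholog triplets and quadruplets with an exact dynamic-programming
    P-value, a binomial criterion for conversions covering entire paralogs,
    collapsing of redundant observations of a single historical event,
    placement of events on a species tree as bounded sub-lineages, and a
    gene-cluster evolution simulator with a sensitivity/false-discovery
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
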