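Package: paralogrisk
Title: Repeat-Mediated Genome Rearrangement Risk from DNA End Resection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the fraction of a genome from which a double-strand break
    can engage a highly similar paralogous gene and thereby mediate a
    chromosomal rearrangement. Implements match-count global alignment
    (longest-common-subsequence) similarity between paralog family members
    with a retention threshold, a resection-exposure interval model giving
    the at-risk genome fraction as a function of time after break formation
    under crossover and one-ended repair geometries, ratio statistics for
    recombination assay quantification with rank-based significance testing,
    and a synthetic-genome and synthetic-assay generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
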