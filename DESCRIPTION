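Package: telomir
Title: Telomere-Anchored Interaction Mining and Telomere-Length-Dependent
    Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for telomere position effects over long
    distances (TPE-OLD): mines recurrent telomere-anchored interactions from
    Hi-C read pairs by tandem TTAGGG-repeat classification, calls
    differentially methylated regions across telomere-length conditions and
    filters them for directional consistency, tests subtelomeric enrichment
    of gene and region sets, scans for a 35-bp consensus motif near
    deregulated loci, and clusters chromosome ends by telomere-associated
    features. Includes a seeded synthetic-data generator so the whole
    pipeline runs and is testable without external downloads.
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
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
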