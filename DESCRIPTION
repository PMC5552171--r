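Package: transposcan
Title: In Silico Transposon Display and Insertion-Site Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying where an endogenous CACTA-family DNA
    transposon lands in a plant genome. The package simulates the
    transposon display assay in silico (blunt-end restriction digestion,
    adaptor ligation and nested PCR band prediction), maps validated
    flanking sequences back to the reference with an exact seed-and-extend
    mapper, partitions gene models (longest splice variant) into 5' UTR,
    CDS, 3' UTR and intron lengths to build the random-insertion
    expectation, classifies insertion sites against the annotation and
    chromatin context, and tests insertion randomness with chi-squared
    statistics plus a sliding-window hotspot sweep. A reproducible
    synthetic-genome generator makes the whole pipeline testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
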