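Package: indelcons
Title: Consensus Calling and Slippage Analysis for Short Coding INDELs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a high-confidence consensus set of short (<100 bp)
    insertion/deletion variants from multiple caller-specific VCF call sets.
    Call sets are normalized (multi-allelic decomposition, complex-event
    splitting, left alignment), merged into an annotated union restricted to
    autosomal target regions, and scored with a random-forest classifier
    trained against a truth overlap; retained alleles are regenotyped under a
    binomial read model. Downstream analyses classify INDELs as
    polymerase-slippage (change-in-copy-count) versus non-slippage events,
    compute per-individual density, allele-frequency-spectrum, heterozygosity
    and frameshift statistics, and evaluate call sets against validation read
    evidence (false discovery rate, relative sensitivity, detectable-INDEL
    estimates, confirmation/rediscovery rates). A synthetic-data generator
    produces references, truth sets, caller call sets and validation evidence
    with known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    withr,
    rtracklayer,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    randomForest,
    Biostrings,
    IRanges,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
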