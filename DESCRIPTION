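Package: pseudocall
Title: Pseudogene-Aware Variant, Copy-Number and Breakpoint Calling for
    Segmentally Duplicated Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for validating variant detection in genes shadowed by
    highly similar pseudogene copies, modelled on the PKD1/PKD1P1-P6 locus.
    Simulates a master gene whose 5' portion is segmentally duplicated into
    pseudogene copies at a controlled sequence identity, plants truth
    variants, simulates paired-end reads, and maps them with a built-in
    seed-and-extend Smith-Waterman mapper so competitive read mapping between
    master gene and pseudogenes is reproducible without external aligners.
    Implements tiered allele-fraction variant calling (standard 20 percent,
    relaxed 8 percent inside the duplicated region, homozygous at 85
    percent), depth-of-coverage copy-number calling against a control panel
    with log2-ratio and control-support thresholds plus a named filter
    ledger, MLPA-style ratio checks, soft-clip extraction with
    sliding-window breakpoint decomposition, and sensitivity/specificity
    evaluation against the planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    GenomicAlignments,
    GenomicRanges,
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
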