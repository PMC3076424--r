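Package: radpe
Title: Local Assembly and SNP Calling for RAD Paired-End Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds per-locus contigs from restriction-site associated DNA
    (RAD) paired-end libraries by binning read pairs on their RAD tag and
    locally assembling the sheared-end reads of each tag with a de Bruijn
    graph whose word length adapts to coverage.  Supports standard RAD SNP
    discovery (threshold genotype calling against the per-tag contigs and
    bi-allelic tag haplotype pairing), partial-digest libraries that tile a
    whole genome with overlapping contigs, and long-insert circularization
    libraries assembled in two passes.  A restriction-digest and library
    simulator with full truth tables makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
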