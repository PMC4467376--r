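Package: editcall
Title: Indel Calling and Off-Target Screening for Somatic CRISPR/Cas9 Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for characterising CRISPR/Cas9 editing
    outcomes in polyclonal tumour samples. Calls insertions and deletions
    from staggered-amplicon paired-end deep sequencing (demultiplex, merge,
    collapse, annotate, threshold), extracts and filters deletions from
    whole-genome sequencing alignments via CIGAR and split-read evidence
    against matched controls, classifies frameshift consequences and
    allele fractions at a target locus, screens the genome for guide-RNA
    protospacer matches within a mismatch budget together with
    recurrence-based off-target filters, and quantifies gene modification
    from SURVEYOR cleavage assays. Ships a seeded synthetic-data generator
    emulating polyclonal edited-tumour sequencing so every stage is
    verifiable against ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
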