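Package: pseudoref
Title: Reference-Guided Pseudomolecule Construction and Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds chromosome pseudomolecules for a resequenced genome by
    anchoring draft contigs onto a related reference, and compares the two
    genomes. Includes a maximal-exact-match seeded whole-genome aligner with
    collinear chaining and banded extension, pileup-based two-round contig
    polishing, BAC-end-sequence and paired-end rescue anchoring of unplaced
    contigs, split-alignment calling of SNPs and large (>=100 bp) insertions
    and deletions with read-support validation, gene presence/absence and
    SNP-effect classification, and unique-mapping-rate reports. A synthetic
    genome simulator with machine-readable truth tables supports end-to-end
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
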