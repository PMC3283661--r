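Package: snparraydesign
Title: Design, Validation and Evaluation of Genome-Wide SNP Genotyping Arrays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building a medium-density SNP genotyping array from
    multi-accession low-coverage resequencing candidates. Implements the
    staged filtering cascade used for the apple 8K Infinium array: hard
    rejection rules over candidate calls (chromosome-end margin, reference
    ambiguity, adjacent SNPs, flanking copy number, allele quality, read
    support, depth outliers, and A/T-C/G transversions), restriction to
    exonic sequence, focal-point cluster design on a genetic map with
    minor-allele-frequency binning and spacing constraints, validation-panel
    selection and GoldenGate-style classification, Infinium-style array QC
    and polymorphism summaries, trio-based haplotype phasing of SNP clusters
    with recombination detection, and a synthetic-data generator with a full
    ground-truth ledger for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    methods,
    stats,
    utils,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
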