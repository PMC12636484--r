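Package: cephsex
Title: Sex Genotyping of Cephalopods by qPCR Chromosome Dosage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for chromosome-dosage sex genotyping in coleoid
    cephalopods (Z0 females, ZZ males). Identifies Z-linked contigs from
    whole-genome alignments (PAF), designs and refines locus-specific qPCR
    primer pairs with nearest-neighbor melting temperatures and in-silico
    specificity scanning, and calls genetic sex from technical-replicate
    Cq tables by detecting the one-cycle (two-fold dosage) difference
    between the sex-linked and autosomal loci. Includes simulators for
    Cq batches and synthetic genomes so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, qPCR, Sequencing, Alignment
RoxygenNote: 7.3.3
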