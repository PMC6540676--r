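Package: aflpcap
Title: In Silico AFLP Bait Design and Capture-Data Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the AFLP (amplified fragment length polymorphism)
    bait-generation protocol on arbitrary genome sequence - double
    restriction digest, Y-adapter amplifiability, size selection and
    selective-nucleotide amplification - and implements the downstream
    sequence-capture analysis pipeline: contig quality control and
    redundancy reduction, reciprocal best-hit orthology, optimal
    aligning-region trimming, low-similarity filtering, phylogenomic
    supermatrix assembly with completeness statistics, and conversion of
    variant calls into IUPAC-coded SNP matrices. A seeded synthetic-data
    generator (random genomes, Jukes-Cantor ortholog families, staggered
    contigs, toy VCFs) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
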