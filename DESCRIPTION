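Package: suppressorSeq
Title: Whole-Genome Resequencing Pipeline for Bacterial Suppressor-Mutation Hunts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mapping suppressor mutations in
    clonal bacterial isolates by whole-genome resequencing. Generates toy
    reference genomes with CDS and tRNA annotation, implants shared (parental)
    and strain-private variants, and simulates short single-end reads with
    substitution errors. Reads are placed by a pigeonhole seed-and-extend
    aligner that suppresses multi-mapped reads, variants are called by a
    strict read-consensus criterion from base pileups, call sets are combined
    across strains into a variant-by-strain matrix to separate parental from
    suppressor-candidate mutations, and protein-level effects are annotated,
    including amber stop-codon gains and suppressor-tRNA readthrough.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    VariantAnnotation,
    Rsamtools,
    SummarizedExperiment,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Alignment, SNP, VariantDetection, Sequencing, Software
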