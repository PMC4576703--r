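Package: driftscape
Title: Diversity, Divergence and Linkage Disequilibrium Across Site
    Classes in Population Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A population-genomic analysis pipeline for multi-sample
    diploid resequencing cohorts: a post-call variant filter stack
    (quality, inbreeding coefficient, modal-coverage bounds, indel and
    CpG-prone masking, variant-proximity filter) producing an explicit
    accessible-site mask; classification of sites by codon degeneracy
    (0-, 2- and 4-fold) and into conserved noncoding element (CNE) sets
    with matched neutral flank references; nucleotide diversity,
    outgroup divergence, pi/d, folded site-frequency spectra with
    hypergeometric projection, Tajima's D and block-bootstrap
    confidence intervals; distance-binned diversity profiles around
    exons and CNEs with distance-kernel convolution and far-field slope
    fits; genotype-based r-squared linkage-disequilibrium decay curves
    with offset plain and stretched exponential fits; effective
    population size and mutation-rate estimation; and export encodings
    for PSMC and DFE-alpha. A forward Wright-Fisher simulator with
    selection, recombination and demography generates fully specified
    synthetic cohorts (VCF, FASTA, GFF3, BED) so every stage can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
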