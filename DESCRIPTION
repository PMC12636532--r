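Package: hybridploid
Title: Allodiploid Hybrid Genome Analysis: Heterozygosity, LOH, Parentage,
    Aneuploidy, Methylation and Isoform Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for phased allodiploid hybrid genomes of
    clonally propagating algae and other vegetatively diploid eukaryotes.
    Computes windowed heterozygosity and divergence from variant calls over
    alignable blocks, calls and classifies loss-of-heterozygosity (LOH)
    tracts, assigns a parent of origin to each genomic window and detects
    reciprocal and nonreciprocal parentage switches, calls whole- and
    partial-chromosome aneuploidy from binned read depth, scans assemblies
    for internal telomeric repeats and AT-rich centromere candidates, builds
    TSS-anchored DNA-methylation metaplots with periodicity estimation, and
    curates IsoSeq-derived gene models (gene decoupling, isoform filtering,
    primary-isoform selection, Kozak-model ORF extension, antisense lncRNA
    classification, gene-ID assignment). A synthetic allodiploid genome
    simulator with fully planted ground truth drives testing of every
    component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
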