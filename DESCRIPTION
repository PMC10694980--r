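Package: introscan
Title: Genome Scans for Adaptive Introgression from Haplotype Sharing
Version: 0.1.0
Authors@R:
    person("Scan", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects haplotypes introgressed between pig populations from
    phased whole-genome SNP data and links candidate haplotypes to litter-size
    breeding values. Implements identity-by-descent (IBD) segment detection on
    phased haplotypes, per-bin normalized IBD sharing (nIBD) and relative IBD
    (rIBD) statistics, windowed Hudson Fst, locus-specific branch length
    (LSBL), Z-transformed heterozygosity (Zhet) selection scans, top-quantile
    region calling with proximity merging, regional haplotype tables,
    minimum-spanning haplotype networks, tag-SNP genotyping of introgressed
    (Q/q) haplotypes, pedigree BLUP breeding values via Henderson's
    mixed-model equations, and one-way ANOVA association of haplotype
    genotypes with breeding values. Ships a three-population simulator with
    planted introgressed tracts and a pedigreed-phenotype generator so every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    ape,
    data.table,
    jsonlite,
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
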