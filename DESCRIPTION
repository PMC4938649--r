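Package: balancerseq
Title: Breakpoint and Crossover Analysis for Multiply Inverted Balancer Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the molecular analysis of balancer chromosomes from
    whole-genome sequencing of balancer/reference heterozygotes. Models
    multiply inverted chromosomes base-exactly (segment maps, coordinate
    liftover, junction deletion/duplication arithmetic), detects inversion
    breakpoints from split and discordant read-pair signatures using 1-kb
    window scanning with soft-clip consensus refinement, and detects single
    and double crossover tracts across a panel of balancer stocks from
    SNP-sharing profiles. Includes a deterministic synthetic-data generator
    (reference, karyotype, stock panel, aligned paired-end and mate-pair
    reads, per-stock VCFs, repeat masks and gene models) with full truth
    records, and a gene-model annotator for bisected genes and small-lesion
    reading-frame classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
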