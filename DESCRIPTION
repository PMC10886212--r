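Package: sweepscan
Title: Selective Sweep Scans from Two-Population SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparative genotype analysis between two
    populations genotyped on a SNP array: quality control (call rate, autosome,
    minor allele frequency, exact Hardy-Weinberg test), population structure
    (allele-frequency PCA, identity-by-state distances, neighbor-joining
    trees), linkage-disequilibrium decay with the r2_0.3 summary, a
    sliding-window selective-sweep scan combining the fixation index FST with
    the nucleotide-diversity ratio under empirical 1% quantile thresholds,
    candidate-SNP annotation against gene models, and hypergeometric gene-set
    enrichment. Ships a two-population Balding-Nichols simulator with planted
    sweep regions so every stage can be exercised against a known truth set.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    fgsea,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
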