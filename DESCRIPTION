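Package: photoclines
Title: Detection of Photoperiod-Driven Selection from Latitude-Structured
    Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting natural selection driven
    by annual photoperiod variation in geographically structured panels of
    human populations. Computes day length and annual photoperiod extremes
    from latitude, scans biallelic variants for Kendall rank correlation
    between allele frequency and delta-photoperiod with minor-allele-
    frequency-binned empirical percentile ranks, evaluates gene-set and
    SNP-set excesses by resampling, measures pairwise Weir-Cockerham
    population differentiation with MAF-class empirical ranks, and applies
    two haplotype-based selection tests: intra-allelic nucleotide diversity
    (DIND) and the cross-population extended haplotype homozygosity ratio
    (lnRsb). A seeded synthetic-data generator produces latitude-stratified
    allele frequencies, genotypes and haplotype panels with planted
    frequency clines and selective sweeps for calibration and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
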