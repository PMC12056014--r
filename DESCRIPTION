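Package: haploscan
Title: Haplotype-Based Selection Scans with Gene-Set Enrichment and
    Branch-Site Test Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recent positive selection in phased population panels by
    combining extended-haplotype-homozygosity statistics (iHS and xpEHH) with
    allele-frequency-binned Weir-Cockerham FST thresholds and a 51-SNP
    extreme-score window rule, maps candidate variants to exonic regions, and
    evaluates focal gene sets by a resampling (random gene set) null and Fisher
    lineage comparisons. Also post-processes branch-site codon-model
    log-likelihoods into likelihood-ratio statistics with halved chi-square
    p-values and Bonferroni correction. Includes a seeded synthetic-data
    generator that produces phased multi-population haplotype panels with
    planted selective sweeps, exon annotations and truth tables, so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
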