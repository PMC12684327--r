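Package: landgen
Title: Landscape Genomics of Local Adaptation and Climate Vulnerability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for landscape-genomic analysis of local
    adaptation in sessile species sampled across an environmental gradient:
    genotype filtering (quality, missingness, transposable-element exclusion,
    linkage-disequilibrium pruning), diversity and differentiation statistics
    (observed/expected heterozygosity, inbreeding coefficient, rarefied
    allelic richness, nucleotide diversity, Tajima's D, Weir-Cockerham F_ST,
    KING kinship), multi-method selection scans (principal-component
    Mahalanobis outliers, F_ST outliers, latent factor mixed models,
    covariance-whitened Bayes factors, redundancy-analysis outliers), a
    multi-method consensus candidate set, gene-proximity GO enrichment, and a
    redundancy-analysis genomic offset projected over current and future
    climate grids with an adaptive-capacity report. A synthetic-data module
    generates landscapes, Balding-Nichols genotypes with planted adaptive
    loci, and future climates so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
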