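Package: gpsmr
Title: Generation Proxy Selection Mapping and Environmental GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps ongoing polygenic selection and local environmental
    adaptation in temporally and spatially stratified genotype panels.
    Implements Generation Proxy Selection Mapping (GPSM), a linear mixed
    model association scan that uses an individual's birth date (or another
    generation proxy) as the dependent variable while controlling for
    relatedness with a standardized genomic relationship matrix, and
    environmental GWAS (envGWAS), the same machinery with continuous
    climate normals or discrete ecoregion membership as the phenotype.
    Includes single- and multi-component REML variance partitioning,
    multivariate scans, Storey q-values, ecoregion derivation by K-means on
    climate normals, fixed-effects meta-analysis of region-specific scans
    with Cochran's Q and m-values, and truth-known validation frameworks:
    a forward-in-time breeding simulator and a pedigree gene-drop null.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
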