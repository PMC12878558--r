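Package: twodeme
Title: Two-Deme Population Genomics: Simulation, Filtering, Diversity,
    Structure, Demography and Environment Association
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for whole-genome population genomics of two
    putative populations (demes) sampled from an all-sites VCF: variant
    filter cascade (site quality, allele balance, per-sample depth bounds,
    missingness), missing-data-aware windowed nucleotide diversity and
    divergence (pi, Watterson's theta, Tajima's D, Dxy, Hudson Fst),
    per-sample heterozygosity, F_IS, runs of homozygosity and F_ROH, linkage
    disequilibrium decay and pruning, population structure (PCA, identity-by-
    state distances, neighbour-joining trees, isolation by distance via
    multiple regression on distance matrices, NMF ancestry estimation with
    masked cross-entropy K selection), folded joint site-frequency-spectrum
    demographic model comparison by simulated composite likelihood and AIC,
    and redundancy-analysis genotype-environment association with outlier
    detection. Includes a structured-coalescent synthetic-data generator
    (two demes under isolation-with-migration, sequencing artifacts,
    latitudinal environment gradients) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
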