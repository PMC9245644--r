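Package: repeatscape
Title: Comparative Repeatome Analysis with Synthetic Benchmarks
Version: 0.1.0
Authors@R:
    person("Repeatscape", "Developers", email = "maintainer@repeatscape.org",
           role = c("aut", "cre"))
Description: Tools for comparing transposable-element landscapes across
    genome assemblies: greedy centroid clustering of repeat consensus
    libraries at a fixed identity threshold, per-genome repeat occupancy
    matrices (by class taxonomy or by sequence-identity cluster) with
    100-kb windowed density tracks, principal-components ordination of
    genomes in repeat space, rank-abundance profiles of repeat clusters,
    resampling-based tests for repeat enrichment around focal gene
    families with empirical p-values and Benjamini-Hochberg FDR control,
    and phylogenetic generalized least squares regression of repeat
    content on genome size under Brownian motion. A fully deterministic
    synthetic-data generator plants repeat landscapes, regional
    enrichments and Brownian traits with known truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
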