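Package: suscape
Title: Read-Depth Copy-Number Landscapes and Copy-Number Phylogenetics
    for Closely Related Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects copy number variable regions (CNVRs) from binned
    whole-genome read depth across a small cohort of closely related
    populations, and asks whether their copy-number landscape tracks the
    species phylogeny. Implements the full read-depth pipeline (1-kb
    binning on a repeat-masked genome, GC-stratum depth correction,
    two-stage diploid calibration, copy-number estimation, multi-copy
    region chaining and cross-population CNVR ascertainment), gene
    annotation with olfactory-receptor partitioning, binary copy-number
    difference and SNP rate comparison, neighbor-joining and hierarchical
    clustering on copy-number distances, and Bayesian phylogenetics on
    discretized copy numbers under the Mkv model with constrained
    topologies and stepping-stone marginal-likelihood model comparison.
    A synthetic-cohort generator with tree-structured copy-number
    evolution, admixture, GC-biased negative-binomial read depth and
    diploid-region SNPs makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    phangorn,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
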