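Package: criollo
Title: Demographic Inference and Selection Scans for Admixed Cattle SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the demographic history of recently
    founded, admixed livestock populations from SNP array genotypes and for
    locating genomic regions under recent positive selection. Implements
    scenario-based approximate Bayesian computation (rejection sampling with
    linear regression adjustment, kernel marginal densities, Bayes factors),
    linkage-disequilibrium based effective population size trajectories with
    a normalized slope statistic (NeS), cross-population extended haplotype
    homozygosity (XP-EHH) and windowed Weir-Cockerham FST genome scans with
    replicate-validated region calling, and a hidden Markov model for local
    ancestry with excess/deficiency scoring at candidate regions. Ships a
    synthetic-data module (structured coalescent, forward Wright-Fisher with
    recombination, admixture track simulation, sweep planting and SNP-array
    ascertainment) so every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
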