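Package: clonepop
Title: Population Genetics of Partially Clonal, Subdivided Populations from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diploid microsatellite genotype data from
    partially clonal, subdivided marine populations such as deep-sea corals.
    Reads and writes GenePop files, detects multilocus genotypes and
    quantifies clonality (P_gen, P_sex, genotypic richness), computes
    per-site diversity with exact Hardy-Weinberg tests by Markov chain,
    estimates and corrects for null alleles, measures differentiation
    (Weir-Cockerham theta, Hedrick's G'ST, Jost's D) with permutation
    significance, hierarchical AMOVA, principal coordinates and Mantel
    isolation-by-distance, moment-based gene-flow estimates (Wright's
    formula, private alleles) and contemporary effective population size by
    the linkage-disequilibrium method, and model-based clustering of
    individuals with replicate runs and Evanno's delta-K. A forward-time
    island-model simulator with asexual reproduction, stepwise mutation and
    heritable null alleles provides ground-truthed synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    geosphere,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
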