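Package: bandpop
Title: Population Genetics from Dominant-Marker Band Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of dominant molecular markers (RAPD, ISSR) scored as
    binary band presence/absence phenotypes. Estimates null-allele and
    band-allele frequencies under Hardy-Weinberg equilibrium, expected
    heterozygosity, percent polymorphism and Shannon diversity; partitions
    molecular variance among and within populations (AMOVA) with a
    permutation test of Phi-ST; computes Gower simple-matching similarity,
    population-averaged similarity tables and principal coordinate analysis;
    fits a Bayesian admixture (STRUCTURE-style) clustering model to binary
    band data by Gibbs sampling with model-size selection by the Evanno
    delta-K statistic; and simulates dominant-marker datasets with known
    differentiation under the Balding-Nichols model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
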