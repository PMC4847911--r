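Package: kinpatch
Title: Kin-Aggregation Analysis of Chaotic Genetic Patchiness from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing chaotic genetic patchiness and testing the
    kin-aggregation hypothesis in codominant (microsatellite) genotype data.
    Implements per-site Hardy-Weinberg exact and homozygote-excess Monte
    Carlo tests conditional on allele counts, inbreeding coefficients with
    permutation significance, null-allele missingness regression, pairwise
    differentiation (proportion of different alleles and Weir-Cockerham
    F_ST) with permutation tests and Holm correction, Mantel
    isolation-by-distance tests, maximum-likelihood pairwise relatedness on
    the IBD-coefficient simplex with a class-II genotyping-error model,
    within-site k-means/BIC genetic clustering with discriminant
    projections, full-sib/half-sib dyad classification with exclusion
    probability power analysis, and sibship-network transitivity tests
    against Erdos-Renyi nulls. A pedigree-structured genotype simulator with
    known truth drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
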