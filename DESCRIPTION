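Package: traitmix
Title: Trait-Based Design and Analysis of Invasion-Resistant Grassland Seed Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing grassland seed mixtures that resist invasion by
    an overabundant native species, and for analysing the resulting suppression
    experiment. Mixture design maximizes Rao's quadratic entropy on one
    standardized functional trait while pinning the community-weighted mean of a
    second trait to the invader's value (an equality-constrained quadratic
    program on the abundance simplex, with a brute-force grid oracle for
    verification). Community descriptors include community-weighted mean traits,
    cutting-tolerance abundance updates across harvest periods, and Faith's
    phylogenetic diversity on a rooted tree. The inference stage standardizes
    biomass per week, screens outliers with an iterative Grubbs test and
    group-mean replacement, rescales predictors, compares mixtures with linear
    models plus Tukey grouping, and fits linear mixed-effects models with type
    III Wald chi-square tests. A synthetic-experiment generator reproduces the
    layout and effect-sign structure of the greenhouse study so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    lme4,
    MASS,
    multcomp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
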