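Package: morbstate
Title: Multimorbidity Burden States, Transitions, and Healthy Life Expectancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for studying how family multi-generational
    relationship patterns relate to multimorbidity onset, progression of
    multimorbidity-burden states, and healthy life expectancy in a
    middle-aged and older panel cohort. Provides a seeded synthetic cohort
    generator mirroring a four-wave CHARLS-like survey design, a weighted
    multimorbidity burden index with exhaustive disease-cluster enumeration
    and exact one-dimensional k-means discretization into ordered states,
    Cox proportional-hazards estimation with Schoenfeld diagnostics, a
    progressive continuous-time Markov multi-state model for
    interval-censored panel states with exactly dated deaths, and multistate
    life tables yielding life expectancy, healthy life expectancy and years
    of healthy life lost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
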