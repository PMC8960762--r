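Package: earmorph
Title: Phylogenetic Comparative Analysis of Avian Middle-Ear Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking bird middle-ear morphology to aquatic
    lifestyles. Computes auditory trait measures (tympanic membrane and
    footplate areas, umbo height, membrane angle, columella offset, lever
    arms) from 3D landmark coordinates; fits allometric phylogenetic
    generalized least squares regressions with maximum-likelihood Pagel's
    lambda and AICc model selection; performs phylogenetic principal
    components analysis of size-corrected residuals; classifies species by
    maximum dive depth; and fits Bayesian phylogenetic cumulative-logit
    models for ordinal interaural-connectivity states. Includes synthetic
    generators for trees, traits, ordinal states and ear geometries with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    optparse,
    jsonlite
Config/testthat/edition: 3
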