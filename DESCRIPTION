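Package: pairedG
Title: Paired-Pedigree Tests of Dominance Effects on Additive Genetic
    (Co)variance Under Inbreeding
Version: 0.1.0
Authors@R:
    person("pairedG", "Developers", email = "pairedg@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether dominance gene action deflates
    additive genetic (co)variance under inbreeding using a paired
    middle-class-neighbourhood (MCN) breeding design.  Provides
    single-locus theory for additive variance under one generation of
    inbreeding, pedigree validation with tabular-method numerator
    relationship matrices (diagonals 1 + F), a simulator for MCN
    populations with explicit multilocus additive and dominance effects,
    landmark morphometrics (generalized Procrustes alignment, centroid
    size, inter-landmark distances, Mahalanobis outlier and paired-sire
    filters), a multivariate average-information REML animal model with
    reduced-rank (factor-analytic) refits, and a G-matrix comparison
    suite based on REML-MVN sampling: variance-ratio confidence
    intervals, eigenprojection, eigenvector dot products, the
    difference-matrix eigentensor, and inbreeding-depression estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
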