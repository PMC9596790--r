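Package: atriasim
Title: Population-Based Simulation of Fibrosis and Drug Effects on Atrial Conduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monodomain simulation of 2D human atrial tissue with diffuse
    fibroblast infiltration and gap-junction coupled myocyte-fibroblast pairs.
    Implements a human atrial cardiomyocyte model with AF-type remodelling and
    an active-fibroblast model, a Latin-hypercube population-of-models workflow
    with biomarker calibration, single-pore-channel antiarrhythmic drug block
    (amiodarone, dofetilide, sotalol), action-potential biomarker extraction
    (APD90, conduction velocity, resting membrane potential, peak amplitude),
    conduction-block labelling, and supervised classifiers (polynomial-kernel
    SVMs, decision tree, k-nearest neighbours) that predict conduction from
    ionic-profile, drug and fibrosis features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    e1071,
    rpart,
    class,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
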