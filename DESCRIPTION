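Package: gfenet
Title: GAN Feature Enhancement for Imbalanced Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting a rare binary clinical outcome from
    high-dimensional clinical and metabolomic feature tables under severe
    class imbalance. Implements an adversarially trained autoencoder
    generator that emits feature-enhanced synthetic minority-class records,
    a discriminator-weighted extension of binary cross entropy (the GFE
    loss) for training a multilayer perceptron on combined observed and
    generated data, from-scratch SMOTE and edited-nearest-neighbour
    resampling with an iterative balancing schedule, an autoencoder
    embedding for generative quality control, a mean-replacement
    sensitivity analysis for feature ranking, and a synthetic cohort
    simulator that reproduces the statistical structure of a
    population-based metabolomics study so the full pipeline is testable
    without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    randomForest,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    MASS
Config/testthat/edition: 3
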