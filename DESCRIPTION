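Package: hsfkit
Title: Hybrid Fluorescence/Reflectance Spectral Fingerprinting for Drug
    Checking
Version: 0.1.0
Authors@R: person("HSF", "Maintainers", email = "hsfkit@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for hybrid spectral fingerprinting (HSF),
    the combination of LED-excited fluorescence emission with the reflected
    excitation line as a diffuse-reflectance "pseudoabsorption" channel,
    as used by portable drug-checking spectrometers. Provides a
    physics-based simulator of the 12-LED device (Beer-Lambert absorbance,
    primary and secondary inner-filter effects, auto-integration to 80%
    detector saturation), the five-step preprocessing pipeline that turns
    an 18,192-row raw scan into a 66 x 66 x 1 fingerprint, a synthetic
    86-class drug/variant/concentration library with oversampling and a
    seeded 80/20 split, and four classifiers over fingerprints: a small
    convolutional neural network plus one-vs-rest logistic-regression,
    random-forest and kernel support-vector baselines with the standard
    hyperparameter grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
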