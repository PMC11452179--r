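Package: rgctwin
Title: Digital-Twin Modelling of Retinal Ganglion Cell Chromatic Feature Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for studying chromatic
    feature detection in the mouse retina with a convolutional "digital twin"
    encoding model. Generates clip-structured dichromatic (green/UV) movie
    stimuli and ground-truth simulated retinal ganglion cell populations,
    preprocesses calcium-like traces into firing-rate estimates, trains a
    factorised two-layer CNN (or linearised LN control) with per-neuron
    Gaussian readouts by Poisson regression, synthesises maximally exciting
    inputs (MEIs) by constrained gradient ascent, characterises them with
    SVD decompositions and difference-of-Gaussians receptive-field fits,
    maps chromatic-contrast tuning surfaces, and quantifies detection of
    ground-to-sky visual context changes with ROC analysis and
    permutation/bootstrap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
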