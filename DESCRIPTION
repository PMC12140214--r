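Package: beetlesieve
Title: Disaggregation, Classification and Open-Set Scoring of Multi-Specimen Insect Photographs
Version: 0.1.0
Authors@R:
    person("beetlesieve", "maintainers", email = "maintainers@beetlesieve.org", role = c("aut", "cre"))
Description: Splits composite photographs of many insect specimens on a light
    background into single-specimen crops (Otsu thresholding, connected-component
    labeling, border clearing and a two-means size filter), trains a pluggable
    image classifier with a tanh-softmax head, label-smoothing cross-entropy,
    a frozen-backbone warm-up epoch and standard augmentations, and scores every
    prediction with a dispersion-based unknown-class (out-of-class) probability.
    Includes leakage-free grouped stratified splits, a leave-one-class-out
    open-set evaluation harness with fold-averaged one-vs-rest ROC curves, and a
    synthetic composite-image generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
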