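Package: sitmotif
Title: Sitting-Behavior States, Motifs, and Low-Back-Pain Prediction from Chair Center-of-Pressure Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes dynamic sitting behavior from four-channel chair
    load-cell recordings. Reduces raw load signals to a 1 Hz center-of-pressure
    (COP) series, segments the series into recurring sitting states by Toeplitz
    inverse-covariance clustering (penalized dynamic-programming state
    assignment alternating with block-Toeplitz sparse precision estimation),
    discovers recurring state motifs by motif-aware state assignment, and
    predicts within-day change in low-back pain with a feature-weighted
    Parzen-window probabilistic neural network tuned by the social spider
    algorithm under nested stratified cross-validation. Includes exact Shapley
    feature attribution, Kruskal-Wallis/Dunn group comparisons, and a synthetic
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
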