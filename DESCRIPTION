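Package: emodrop
Title: Emotion Classification from Health Text with Intelligent Water
    Drop Feature Selection and a Backpropagation Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting patient emotions in short
    health-related texts. Provides corpus readers and writers, a five-step
    text-cleaning chain (lowercasing, punctuation stripping, stop-word,
    common-term and rare-term removal), n-gram bag-of-words vectorization
    with optional TF-IDF weighting, class-imbalance resampling, a wrapper
    feature selector based on the Intelligent Water Drops (IWD) swarm
    metaheuristic, a from-scratch three-layer sigmoid backpropagation
    neural network trained on a squared-error objective with RMSE-driven
    hidden-size selection, and one-vs-rest multiclass evaluation
    (accuracy, sensitivity, specificity, F-measure). A seeded synthetic
    corpus generator with planted class keywords supports benchmarking and
    feature-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
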