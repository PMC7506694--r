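Package: vagfrm
Title: Frequency Range Map Feature Selection for Vibroarthrographic Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral band feature engineering for vibroarthrographic (VAG)
    knee-joint signals. Implements four band-summed spectral feature families
    (magnitude, derivative-weighted magnitude, energy, derivative-weighted
    energy), a Bhattacharyya-coefficient class-separability measure computed
    over Gaussian kernel density estimates with the Silverman bandwidth, and
    an iterative coarse-to-fine Frequency Range Map (FRM) search that selects,
    for every pair of five joint-condition classes, the frequency band whose
    feature best separates the pair. The ten pairwise-optimal band features
    feed a repeated-random-split multi-classifier benchmark against classical
    band-power comparator features. A synthetic VAG generator with
    class-dependent band-limited vibration content makes the whole pipeline
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    MASS,
    e1071,
    class,
    rpart,
    randomForest,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
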