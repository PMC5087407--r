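Package: ockra
Title: One-Class K-Means Ensembles with Random Feature Projections for
    Wearable-Sensor Risk Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies OCKRA, an ensemble of one-class classifiers in
    which each member clusters a random feature projection of the training data
    with k-means++ and scores new observations by a Gaussian kernel of the
    distance to the nearest cluster centroid. Includes preprocessing of
    multi-rate wearable sensor logs (accelerometer, gyroscope, heart rate,
    pedometer, skin temperature, UV) into per-second 26-dimensional feature
    vectors, Parzen-window and centroid-based baseline one-class classifiers
    plus a one-class SVM adapter, per-subject five-fold cross-validated ROC and
    precision-recall evaluation with population curve averaging and paired
    nonparametric tests, and a synthetic wearable-data generator covering
    normal daily behavior and five staged anomaly scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    e1071,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
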