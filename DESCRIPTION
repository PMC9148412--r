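Package: ppbn
Title: Sleep Posture Recognition with a Constrained Bayesian Transition Model
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recognition and one-step-ahead prediction of in-bed sleep
    postures (supine, prone, left and right lateral recumbent) from
    pulse-point pressure images and heartbeat traces. Provides
    preprocessing of 64x64 pulse images (min-max standardization,
    intensity threshold filtering, Gaussian smoothing, rotation-PCA
    alignment), moving-average plus PCA decomposition of heartbeat signal
    matrices, histogram-of-oriented-gradients descriptors with
    pressure-weight normalization, a nearest-centroid frame classifier,
    and a posture-transition Bayesian predictor with anatomically
    motivated structural zeros (prone is entered only from a lateral
    posture, lateral postures only from supine). A seeded synthetic-data
    generator builds constrained Markov posture sequences whose
    stationary occupancies and shift rate match published
    accelerometer-cohort statistics, plus posture-conditioned images and
    heartbeat series, so the whole pipeline is exercisable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, tiff
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
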