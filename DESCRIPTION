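Package: propriolearn
Title: Proprioceptive Psychophysics Scoring and Behavioural Causal Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for studying how proprioceptive short-term memory and
    proprioceptive acuity relate to passively guided motor learning.
    Implements signal-detection scoring (sensitivity, precision, d-prime,
    serial-position sensitivity) of an angle recognition-memory task,
    maximum-likelihood cumulative-Gaussian fitting of a 2AFC angle
    discrimination task with just-noticeable-difference estimation,
    peak normalized cross-correlation and RMSE scoring of reproduced
    elbow-joint trajectories, DirectLiNGAM causal discovery with
    adaptive-LASSO pruning, bootstrap edge probabilities and HSIC /
    Shapiro-Wilk assumption checks, and maximum-likelihood path-model
    (SEM) re-fitting with standard fit indices.  A calibrated
    synthetic-cohort generator produces trial-level data with the same
    task designs and latent structure, so every stage of the pipeline can
    be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
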