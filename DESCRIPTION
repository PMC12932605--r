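Package: runload
Title: Structure-Specific Musculoskeletal Load Estimation from IMU Data During Running
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates stance-phase structure-specific loads (Achilles tendon,
    patellar tendon, ankle and knee joint contact forces) during treadmill
    running from dual inertial measurement unit (IMU) streams. Provides a
    synthetic-cohort generator with ground-truth load curves, quaternion-based
    angular velocity computation, threshold gait-event detection, vertical
    ground-reaction-force step segmentation with exclusion rules, a tabular
    biomechanical feature battery, bidirectional LSTM and feed-forward
    regression models trained with Adam and early stopping, subject-level
    five-fold cross-validation, and Monte Carlo dropout uncertainty
    quantification for load curves and their derived characteristics (peak,
    impulse, average loading rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    glmnet,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
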