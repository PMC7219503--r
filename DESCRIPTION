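Package: armrehab
Title: Computerized Assessment of Shoulder Rehabilitation Exercises from
    Skeleton Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assesses the correctness of right-arm shoulder exercises
    (flexion, horizontal abduction/adduction, adduction) recorded as
    Kinect-style 25-joint skeleton tracking sessions. Extracts 38
    view-invariant angle- and joint-based features per frame in a
    body-attached anatomical coordinate system, classifies sessions by
    average multidimensional dynamic time warping distance to
    participant-specific gold-standard session banks, optimizes the
    feature subset by recursive backward elimination, and evaluates the
    assessment with repeated stratified tenfold cross-validation
    (accuracy, specificity, sensitivity, Cohen's kappa) together with
    feature-occurrence summaries. Includes a forward-kinematics session
    simulator that generates correct and impairment-perturbed exercise
    executions so the full pipeline can be exercised without motion
    tracking hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
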