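Package: propriotask
Title: Task-Driven Neural Network Models of Proprioception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes muscle-spindle input datasets from single-stroke
    character trajectories via explicit four degree-of-freedom arm kinematics
    and a configurable 25-muscle geometry, trains small convolutional and
    recurrent networks on action-recognition and trajectory-decoding tasks,
    and provides the accompanying single-unit (directional, positional, speed
    and label tuning) and population-level (centered kernel alignment,
    representational similarity, preferred-direction uniformity and
    invariance, population decoding) analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    e1071,
    pROC,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
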