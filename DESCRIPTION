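Package: templatesig
Title: Data-Driven Template Signatures of Center-of-Mass Dynamics in Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies individual-specific template signatures -- sparse sets
    of physically interpretable mechanisms (leg springs, leg dampers, sagittal-
    and frontal-plane rotary spring-dampers) that describe whole-body
    center-of-mass accelerations during walking -- from center-of-mass and foot
    trajectories.  Implements phase-based clustering of hybrid gait regimes,
    sequential thresholded least-squares sparse regression over a mechanism
    library, AICc-based model selection with Akaike-weight multi-model
    averaging, and bootstrap quantification of coefficient uncertainty.  A
    forward simulator of a three-dimensional bipedal spring-loaded inverted
    pendulum augmented with damping and rotary mechanisms provides ground-truth
    synthetic gait data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    splines,
    Matrix,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
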