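Package: sectornet
Title: Lightweight Detectors for Fetal Echocardiography Standard Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A construction kit for a family of resource-efficient one-stage
    detectors of fetal ultrasound standard sections (abdominal transverse,
    four-chamber, outflow tract and three-vessel views). Provides the neural
    building blocks (hard-swish activations, squeeze-and-excitation, inverted
    residual bottlenecks, fast spatial pyramid pooling), a declarative model
    graph with pruning-based derivation of five sized variants, exact
    trainable-parameter accounting calibrated against the published model
    series, YOLO-format dataset tooling, an ultrasound-like synthetic scene
    generator with multiplicative speckle, the standard detection metric stack
    (precision, recall, mAP at IoU 0.5), and a small CPU training and
    inference engine with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
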