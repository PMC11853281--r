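Package: neomotion
Title: Non-Contact Neonatal Activity Monitoring from Depth Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Converts depth-camera video of a neonate into per-second
    motion / no-motion classifications. Implements temporal median
    averaging of the depth stream, a five-stage noise-removal cascade
    (percentile clipping, one-second depth differencing, masked spatial
    median filtering, large-difference removal and small-region removal),
    sixteen engineered per-second features, a Random Forest motion
    classifier, and a per-subject leave-one-out cross-validation protocol
    with ROC optimal-operating-point threshold transfer. Includes a
    synthetic depth-scene generator (neonate-like surface, respiratory
    modulation, intermittent limb/torso motion events, depth-sensor
    noise) so the full pipeline can be exercised end to end without any
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    jsonlite,
    yaml,
    e1071,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
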