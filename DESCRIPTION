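Package: pulocalize
Title: Small-Object Localization from Sparse Point Annotations by
    Positive-Unlabeled Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Localizes dense small objects (cell nuclei, insects, crowd
    heads) in raster images from very sparse point annotations.  Builds
    redundant count maps from point-impulse location maps, trains a small
    encoder-decoder regressor under a non-negative positive-unlabeled
    (PU) risk, models unlabeled-region losses with a two-component beta
    mixture to pseudo-label hidden positives, and refines the model with
    an ordinary positive-negative stage.  Objects are reported as
    prominent local maxima of the predicted location map and scored with
    distance-thresholded precision/recall/F1 and mean localization error.
    Includes a synthetic scene generator so the whole pipeline is
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
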