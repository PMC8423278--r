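Package: mcftrack
Title: Graph-Based Cell Tracking by Coupled Minimum-Cost Flow with
    Automatic Segmentation Error Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tracking-by-detection for 2D and 3D time-lapse microscopy.
    Instance segmentation masks are linked over time by solving a coupled
    minimum-cost flow problem on a typed graph whose nodes model movement,
    mitosis, appearance, disappearance and the segmentation errors false
    negative, over-segmentation and under-segmentation. A post-processing
    step untangles the resulting lineage graph with an integer linear
    program (edge removals, track splits, track merges) and fills false
    negative gaps with linearly interpolated masks. Includes a synthetic
    ground-truth generator, a segmentation-error simulator and Cell
    Tracking Challenge style SEG/DET/TRA evaluation measures, so the whole
    pipeline can be exercised without external data. Ships a small exact
    mixed-integer linear programming solver (bounded-variable simplex plus
    branch and bound) used by both optimization stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    ggplot2,
    withr
Config/testthat/edition: 3
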