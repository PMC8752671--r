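Package: cognatevid
Title: Video-Based Classification of Cognate T Cell-Dendritic Cell Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to classify CD8+ T cells as making cognate or non-cognate
    contacts with dendritic cells (DCs) from two-channel time-lapse microscopy.
    Includes an agent-based simulator of T cell-DC co-cultures with ground-truth
    tracks and contact intervals, a nearest-neighbour cell tracker with
    TrackMate-compatible CSV import, the per-cell video pipeline (moving
    101x101 px crop, neighbour masking, Gaussian blur, Huang/Otsu binarization,
    frame sampling), five classical interaction metrics (overlapped pixels, red
    pixels, speed, circularity, interaction time) with ROC/AUC evaluation, and
    a natively implemented time-distributed CNN-LSTM binary classifier with
    Grad-CAM interpretation and a frame-count ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
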