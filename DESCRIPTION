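Package: pseudosegrt
Title: Semi-Supervised Pseudo-Labelling for Retinal OCT Boundary Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised boundary segmentation of retinal optical
    coherence tomography (OCT) B-scans from very few annotated images.
    A small U-Net is pre-trained on a handful of labelled scans, then
    continued jointly with confidence-thresholded trinary pseudo-labels
    on unlabelled scans, using a masked binary cross-entropy and an
    adaptive pseudo-label loss weight refreshed every epoch.  Includes a
    synthetic OCT phantom generator (healthy and distribution-shifted
    variants), fully supervised and classic pseudo-labelling baselines,
    mean-IoU / pixel-accuracy evaluation, and export of the trained
    network to the ONNX interchange format with a numerical parity check.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
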