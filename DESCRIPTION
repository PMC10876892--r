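Package: rdmap
Title: Weakly-Supervised Localization and Postural Guidance for Retinal
    Detachment on Ultra-Widefield Fundus Images
Version: 0.1.0
Authors@R:
    person("rdmap", "developers", email = "rdmap@example.org", role = c("aut", "cre"))
Description: Tools for localizing retinal detachment (RD) on ultra-widefield
    fundus images with only image-level supervision, and for turning the
    localization into preoperative postural guidance. Provides a seeded
    synthetic fundus generator with exact ground-truth lesion masks; region of
    interest masking and contrast-limited adaptive histogram equalization
    (CLAHE); a staged convolutional RD classifier trained with focal loss and
    fine-tuned with channel attention modulation modules; gradient-weighted
    class activation mapping (Grad-CAM) to derive per-pixel probability maps
    and pseudo-masks; a fovea/optic-disc calibrated anatomical frame with four
    clock-hour zones, a posterior-pole circle and 48 partitions; posture rules
    keyed to the affected zone; and evaluation statistics (precision, recall,
    F1 with Wilson confidence intervals, sensitivity, specificity, accuracy,
    precision-recall curves with average precision, unweighted Cohen's kappa,
    confusion matrices, mask intersection-over-union).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
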