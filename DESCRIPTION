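Package: octmap
Title: Automated Mapping and Scoring of Coronary Calcium in Intravascular OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated detection and clinical quantification of
    calcified coronary plaque in polar-coordinate intravascular optical
    coherence tomography (OCT) pullbacks. Provides a seeded synthetic phantom
    generator with ground-truth pixel labels; polar preprocessing including
    log compression and a depth-resolved attenuation-coefficient channel;
    training-time artifact augmentation (non-uniform rotational distortion,
    radial motion, multiple reflection); a UNet-like ten-class pixel segmenter
    with a compiled forward/backward pass and a cross-entropy plus soft-Dice
    training objective; calcium quantification (arc, minimum and maximum
    thickness, lesion length, OCT-calcium score with severity
    dichotomization); and evaluation statistics (per-class ROC/AUC, Youden
    thresholds, plaque confusion matrices, one-dimensional Dice overlap of
    arcs, and Pearson/Spearman/intraclass-correlation agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
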