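Package: ffrwire
Title: Reduced-Order Fractional Flow Reserve Prediction with Pressure
    Guidewire Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based prediction of fractional flow reserve (FFR) on
    reduced-order coronary artery networks. Implements the full pipeline:
    baseline coronary flow distribution (Murray and vessel-length criteria),
    peripheral resistance calibration from a resting steady state, hyperemic
    pulsatile simulation with five-element coronary-bed Windkessel outlet
    models driven by a left-ventricular pressure waveform, and FFR extraction
    as the ratio of cycle-averaged distal to aortic pressure. Vessel segments
    carry Poiseuille or annular (guidewire-included) viscous resistance and a
    Young-Tsai-type stenosis pressure-loss model, so paired wire-absent /
    wire-included predictions can be compared. Includes a synthetic coronary
    tree generator with Murray-consistent radii, a cohort builder calibrated
    to span four invasive-FFR severity classes, and diagnostic evaluation
    (Bland-Altman agreement, sensitivity/specificity/accuracy, ROC AUC)
    against invasive measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    optparse
Config/testthat/edition: 3
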