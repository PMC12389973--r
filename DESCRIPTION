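Package: corticlass
Title: Cortical-Source EEG Depression Classification with Adversarial
    Domain Adaptation
Version: 0.1.0
Authors@R:
    person("Corticlass", "Developers", email = "corticlass@example.org",
           role = c("aut", "cre"))
Description: A multi-stage pipeline for classifying depression from
    resting-state EEG. Reconstructs cortical source activity with the
    sLORETA standardized minimum-norm inverse, extracts multi-band
    linear and nonlinear features on atlas regions of interest
    (phase-locking-value brain networks, clustering coefficient, local
    efficiency, band power, sample and fuzzy entropy), and classifies
    with an attention-enhanced graph convolutional network trained
    under focal loss, center loss and gradient-reversal adversarial
    domain adaptation. Includes a synthetic EEG generator emulating
    multi-subject class-imbalanced resting-state datasets so the whole
    pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
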