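Package: skcsd
Title: Single-Cell Kernel Current Source Density Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the spatiotemporal distribution of transmembrane
    current sources along a neuron of known morphology from simultaneous
    extracellular potential recordings at arbitrarily placed electrodes
    (the single-cell kernel current source density, skCSD, method). The
    morphology is read from SWC files and covered by a closed curve (the
    morphology loop) on which Gaussian current-source basis functions are
    placed; a kernel ridge (Tikhonov) solve in electrode space maps the
    measured potentials back to current sources on the cell. Includes
    forward modelling of extracellular potentials from prescribed current
    distributions, a synthetic ground-truth generator (test morphologies,
    electrode layouts, cosine and synaptic-event current patterns,
    calibrated noise), reconstruction-quality metrics (L1 error against
    Gaussian-smoothed ground truth), leave-one-out cross-validation and
    grid search over basis width and regularization strength, and
    spike-triggered-average preprocessing of paired intra-/extracellular
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
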