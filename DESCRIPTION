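Package: ashca
Title: Stimulus-Evoked Calcium Dynamics in the C. elegans ASH Neuron
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates cytosolic and endoplasmic-reticulum calcium dynamics of
    the C. elegans ASH polymodal sensory neuron in response to arbitrary
    stimulus protocols, converts simulated calcium to percent FRET ratio
    change via a two-point Hill calibration, performs in-silico knockouts of
    individual transport components (PMCA, SERCA, TRPV, IP3R, VGCC), and
    estimates model parameters from cohort FRET traces with a hybrid genetic
    algorithm plus damped Gauss-Newton least squares, including plausible
    parameter-combination enumeration and perturbation sensitivity scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
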