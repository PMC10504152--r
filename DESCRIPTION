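Package: b0predict
Title: Forward Simulation of Motion-Induced B0 Field Inhomogeneities in Head MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict static-field (B0) inhomogeneity maps of the human
    head at arbitrary rigid head positions from a single reference measurement.
    The package builds subject-specific multi-class susceptibility models from
    UTE-like proton-density images by histogram thresholding, computes
    susceptibility-induced fields with a Lorentz-corrected Fourier dipole
    approximation, decomposes measured dual-echo gradient-echo field maps into
    shim, tissue, phase-error and out-of-volume dipole components, refines
    per-segment susceptibilities by bounded least squares, predicts field maps
    at new head positions by transformed, simulated and combined strategies
    (including a body-mask update for large motion), and optimises multi-coil
    shim currents under per-coil and total current limits. A seeded digital
    head phantom generator emulates every input so the whole pipeline can be
    exercised and validated without scanner data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
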