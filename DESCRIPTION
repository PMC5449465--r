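Package: sdbmi
Title: State-Dependent Decoding for Bidirectional Brain-Machine Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates state-dependent spike-count decoding for a
    closed-loop bidirectional brain-machine interface. Generates synthetic
    spike sessions in which a latent cortical-state process additively
    modulates evoked responses, discretizes spike trains with an adaptive
    pre-stimulus binning schedule, fits a PCA plus multiclass linear
    discriminant decoder with winner-take-all posterior thresholding under
    leave-one-out cross-validation, quantifies performance as shuffle-corrected
    confusion-matrix mutual information, and closes the loop around a simulated
    point mass in a viscous medium driven by a posterior-weighted force field.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
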