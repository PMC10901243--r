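Package: polaxis
Title: Mueller Matrix Polarimetry and Fast-Axis Orientation Statistics for Fibrous Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis pipeline for transmission Mueller matrix
    imaging of fibrous samples. Simulates a dual-rotating quarter-wave-plate
    polarimeter (30 frames, 6/30 degree steps), reconstructs per-pixel Mueller
    matrices by least squares, applies the Lu-Chipman polar decomposition to
    obtain fast-axis orientation, linear retardance, depolarization power and
    diattenuation maps, and analyses the axial (180-degree periodic) frequency
    distribution of orientation angles: peak finding, angular FWHM, and the
    classification of bimodal fast-axis distributions into intrinsic- and
    form-birefringence components with their mixing share. Includes a
    synthetic-phantom generator emulating glass fiber, air-dried tendon and
    silk samples, layer stacks and stretching series, with ground truth for
    recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
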