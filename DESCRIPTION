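Package: chromocal
Title: Colorimetric Well-Plate Calibration and Quantification of Hexavalent Chromium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based colorimetric chemosensing of hexavalent
    chromium (Cr(VI)) in water with the TMB-H2O2 chromogenic reaction read on
    scanned 96-well plates. Locates wells on a plate raster, reduces each well
    to RGB channel statistics, fits linear calibration curves with standard
    errors and detection limits (LOD/LOQ), selects the most informative colour
    channel, reading time and reagent dose, inverts calibrations to
    concentrations with an out-of-range (non-detectable) rule, and computes
    spike-recovery and paired method-comparison metrics. Includes a seeded
    synthetic-plate generator with known ground truth and a command-line
    interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
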