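Package: saxsred
Title: Solution X-Ray Scattering Data Reduction and Beamline Operations Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reduction of solution small- and wide-angle X-ray scattering
    (SAXS/WAXS) data from pixel-array detectors: detector-geometry mapping of
    pixels to scattering vector q, azimuthal averaging by histogramming,
    sample-to-detector distance calibration against powder standards,
    multi-detector merging, buffer subtraction anchored on the water
    scattering peak near 2 inverse Angstroms with over-subtraction
    diagnostics, and in-line SEC-SAXS processing including chromatograms and
    singular-value-decomposition removal of time-dependent background.
    Includes synthetic-data generators (form factors, rendered detector
    images, SEC runs with drifting background) and instrument-performance
    calculators (radiation dose, fluidics, dual-channel scheduling, sample
    sheet validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
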