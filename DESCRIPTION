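Package: oleoscan
Title: Scanning-SAXS and Micrograph Orientation Analysis of
    Ultrasound-Structured Oleogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of ultrasound-standing-wave (USW)
    structured monoglyceride oleogels. Reduces scanning small-angle X-ray
    scattering (SAXS) patterns on a (q, chi) grid to radial and azimuthal
    profiles; extracts lamellar d-spacing (Bragg), Scherrer correlation
    length from peak width, Porod power-law exponent and surface-fractal
    dimension, and the Hermans orientation factor; assembles per-point
    results into spatial maps and detects the nodal-band periodicity
    imprinted by the standing wave. A parallel 2D-FFT pipeline quantifies
    platelet orientation in bright-field micrographs via angular power
    spectra. Includes synthetic-data generators with known ground truth
    for every stage, a simple scan-container format, and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
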