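Package: peakmap
Title: Peak Detection, Parameterization and Activation Mapping for
    Physiological Time Series and Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and parameterizes peaks (action potentials, calcium
    transients, contractions) in one-dimensional time series and, per pixel,
    in multi-frame image stacks such as cardiac optical-mapping or confocal
    calcium recordings.  Produces per-event tables (amplitude, time to peak,
    FWHM, FW10, area, maximal slopes, exponential decay constant), isochronal
    activation maps, conduction-velocity vector fields and averaged parameter
    maps, together with a synthetic-signal simulator that provides analytic
    ground truth for validation.  Includes delimited-text and TIFF readers,
    float-TIFF/PNG/CSV writers with a reproducibility manifest, and a
    command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    optparse,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
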