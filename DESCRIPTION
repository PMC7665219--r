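Package: rmclass
Title: Reflection-Matrix Microscopy Simulation and CLASS Aberration Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of laser-scanning reflection-matrix microscopy
    (time-gated, focused-illumination coherent imaging through an aberrating
    layer) and computational adaptive optics by the closed-loop accumulation of
    single scattering (CLASS) algorithm. Provides analytic acquisition planners,
    phase-screen and phantom generators, construction of space- and
    spatial-frequency-domain reflection matrices, iterative retrieval of input
    and output pupil aberrations (global and locally varying variants with
    isoplanatic-patch tiling and stitching), aberration-corrected confocal
    image reconstruction, and point-spread-function quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
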