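Package: valveform
Title: Single-Cell Kinetics and Morphometry of Diatom Valve Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify pH-dependence of silica valve formation in
    centric diatoms from fluorescence time-lapse and transmission electron
    microscopy. Implements cell tracking with local background estimation,
    level-line (iso-intensity) shape extraction, two-phase exponential
    kinetics fitting of valve-formation reporter dyes, a three-fraction
    weak-base dye partitioning model of the silica deposition vesicle,
    Voronoi/Delaunay pore morphometry of valve nanopatterns, growth-rate and
    silicon-quota arithmetic, and ratiometric intracellular pH calibration.
    Ships synthetic-data generators with known ground truth for validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    EBImage,
    deldir,
    minpack.lm,
    jsonlite,
    tiff,
    png,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
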