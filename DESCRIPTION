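Package: poloidal
Title: Poloidal Orientation Analysis of DNA Minicircles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct coarse-grained DNA minicircle geometries from
    helical parameters, measure the poloidal (inside-out) orientation of a
    tracked phosphate along simulated minicircle trajectories using circular
    statistics, fit fixed-period sinusoids to insert-position series to extract
    helical phasing, and analyse atomic force microscopy height maps of
    DNA-protein complexes (background flattening, segmentation, centroid versus
    centre-of-mass offset distance, and relative binding affinity). Includes
    synthetic-data generators with known ground truth for minicircle
    trajectories, AFM scenes and insert-position series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    EBImage,
    png,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
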