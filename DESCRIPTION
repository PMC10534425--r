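Package: sfdical
Title: Model-Based Geometric and Intensity Calibration for Spatial Frequency Domain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step calibration and correction toolkit for spatial frequency
    domain imaging (SFDI) systems built around the pinhole camera model for both
    the projector and the camera. Provides phase-shift demodulation of fringe
    image stacks, circle-grid geometric calibration with phase-encoded projector
    correspondences, per-pixel cubic phase-distance conversion to 3D topography,
    surface-normal and projection/detection-angle estimation, position- and
    orientation-dependent spatial-frequency and Lambert intensity corrections, a
    per-pixel modulation transfer function look-up table, diffuse reflectance
    computation against a reference standard, and least-squares inversion of a
    diffusion-approximation forward model for the absorption coefficient mu_a and
    reduced scattering coefficient mu_s'. A digital-twin simulator renders
    synthetic fringe measurements of planes, spherical caps and calibration
    targets with known ground truth, so the full pipeline can be exercised and
    validated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    generics,
    jsonlite,
    minpack.lm,
    tibble,
    tiff,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
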