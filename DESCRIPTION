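Package: xrpdscreen
Title: Screening for In Cellulo Protein Microcrystals by SAXS/X-Ray Powder Diffraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects protein microcrystals grown inside insect cells from
    small-angle X-ray scattering / X-ray powder diffraction screening data.
    Reduces 2D detector frames to 1D powder profiles by azimuthal integration,
    detects Bragg-peak fingerprints against the cellular background, clusters
    profiles into crystalline phases by principal component analysis, refines
    unit-cell parameters by Pawley whole-powder-pattern fitting (pseudo-Voigt
    peaks, Chebyshev background, zero shift, free per-reflection intensities),
    and estimates detection limits from 1:2 dilution series. A synthetic-data
    generator emulates the beamline experiment (cellular background decay,
    granular Debye-Scherrer rings, Poisson counting noise, paired sample and
    buffer frame series) so the full pipeline is testable without beamline data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    tiff,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
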