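Package: tipix
Title: Quantification of Titanium Micro-Particles in Micro-PIXE Elemental Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify metal micro-particles in elemental count maps of
    peri-implant soft tissue acquired by micro proton-induced X-ray emission
    (micro-PIXE) mosaic scans. Provides a synthetic phantom generator (tissue-shaped
    sulfur background, titanium particles with configurable size, shape and zonal
    density, Gaussian beam blur and fluence-scaled Poisson counting noise), a
    two-pass particle detector (survey-pass blob identification, high-statistics
    confirmation, false-detection threshold calibration, segmentation), per-particle
    morphometry (area, equivalent diameter, Feret calipers, circularity),
    zonal region-of-interest analysis relative to the implant/tissue interface and
    mucosal margin, volumetric particle densities, and the paired nonparametric
    statistics used to compare peri-implantitis and reference implant sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
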