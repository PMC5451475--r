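Package: octaquant
Title: Quantification of Retinal Capillary Metrics from OCT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automated quantification of en-face optical coherence tomography
    angiography (OCT-A) images of the superficial capillary plexus. Implements
    non-local means denoising, Phansalkar adaptive local thresholding, foveal
    avascular zone (FAZ) segmentation by region growing with area, perimeter
    and circularity measurement, vessel density on the ETDRS grid with a
    minimum non-perfusion area rule, skeleton-based box-counting fractal
    dimension and vessel diameter index, and the repeatability statistics
    (intraclass correlation, coefficient of repeatability, Bland-Altman
    limits of agreement, ICC precision planning) used to validate such
    measurements. A synthetic angiogram generator with analytic ground truth
    makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
NeedsCompilation: yes
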