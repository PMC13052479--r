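Package: holocyto
Title: Real-Time Holographic Cytometry Phase Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for high-throughput quantitative phase
    microscopy of flowing cells (holographic cytometry): off-axis
    interferogram demodulation by Fourier sideband cropping, parallel
    block-wise Goldstein branch-cut phase unwrapping, temporal and
    polynomial background removal, correlation-kernel cell detection,
    angular-spectrum digital refocusing with amplitude-variance autofocus
    and a quadratic focus-versus-position calibration, red-blood-cell
    morphometry (projection area, optical volume, eccentricity,
    circularity), and a refocusing-quality evaluation harness (SSIM,
    optical-path-length RMSE, morphological error statistics). Includes a
    seeded synthetic interferogram generator with ground truth so every
    stage is testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
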