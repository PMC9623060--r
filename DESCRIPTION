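Package: wtmmaniso
Title: Multiscale Image Anisotropy via 2D Wavelet Transform Modulus Maxima
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies directional organization in grayscale images (for example
    collagen fibers in second harmonic generation microscopy) across a continuous
    range of size scales using the 2D wavelet transform modulus maxima (WTMM)
    anisotropy method. Computes Gaussian-derivative wavelet transforms over a
    geometric scale ladder, detects modulus maxima along the local gradient
    direction, organizes them into edge-detection maxima chains, bins the
    gradient angles into probability density functions under fixed or
    sample-adaptive (variable) binning, and summarizes each scale by an
    anisotropy factor measuring the deviation from the flat isotropic density.
    Includes synthesis of isotropic calibration fields (white noise and
    fractional Brownian surfaces by Fourier filtering), white-noise
    normalization of anisotropy curves, edge-effect central-crop analysis,
    and per-scale Wilcoxon rank-sum comparisons between image groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
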