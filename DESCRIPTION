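Package: fibrotex
Title: Color-Space Texture Analysis of Liver Fibrosis Histology
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Texture-based classification of normal versus fibrotic liver
    histology across three color spaces (grey scale, RGB, HSI) and three
    image resolutions. Implements grey-level co-occurrence matrix (Haralick)
    features, run-length matrix statistics in four directions, wavelet
    subband energies, Fisher-coefficient feature selection, and unsupervised
    two-class scoring with per-group percentage error, together with a
    synthetic generator of Masson's-trichrome-like liver images so the full
    pipeline is testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    optparse,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
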