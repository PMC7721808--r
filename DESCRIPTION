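Package: pics
Title: Phase Imaging with Computational Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free quantification of sub-cellular dry mass by
    phase imaging with computational specificity (PICS). The package simulates
    gradient light interference microscopy (GLIM) acquisitions of synthetic
    adherent-cell scenes, reconstructs quantitative phase from four
    phase-shifted intensity frames (phase-shifting demodulation followed by
    Fourier-domain integration of the shear gradient), trains a compact
    residual U-Net that predicts fluorescence channels (nucleus / cell body)
    from phase images, and quantifies compartment-specific dry mass,
    confluence, nuclear-cytoplasmic ratio and growth curves from the
    predicted specificity maps. The neural network, including backpropagation
    and the ADAM optimiser, is implemented in pure R on top of BLAS matrix
    products, so the whole pipeline runs without external deep-learning
    frameworks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
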