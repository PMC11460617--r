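Package: holopnp
Title: Lensless Inline Holographic Microscopy with Physics-Aware
    Plug-and-Play Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for lensless digital
    inline holographic microscopy. Provides an angular-spectrum scalar
    diffraction forward model with coherence-limited resolution
    calculators, seeded synthetic phantoms (spherical-cap microbeads and
    cell-like phase objects) with paired hologram datasets, classic
    single-shot backpropagation with autofocus and two-dimensional phase
    unwrapping, and a plug-and-play ADMM reconstruction that couples a
    physics data-fidelity term with a pluggable prior (file-based,
    total-variation, or interpolation) and an untrained encoder-decoder
    image generator to recover twin-image-suppressed, upsampled
    quantitative phase from a single hologram. Includes phase-SNR, SSIM
    and thickness evaluation utilities and a command-line interface for
    config-driven runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
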