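Package: enkit
Title: Time-Encoding Kernel Layers for EEG Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the encoding kernel (EnK), a trainable time-encoding
    layer that decomposes a multichannel signal into additive periodic,
    seasonal, and artifact components and can be inserted after the first
    convolution of standard EEG classification networks (EEGNet,
    ShallowConvNet, DeepConvNet, and a recurrent convolutional network).
    Includes a seeded synthetic EEG epoch generator (event-related
    potentials, band-limited oscillations, 1/f background, ocular and line
    artifacts), a stratified training and evaluation protocol with Adam and
    early stopping, mean-squared-error and F1 metrics, Grad-CAM
    interpretability maps with raw-signal overlays, and a reproducible
    end-to-end pipeline driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rhdf5,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
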