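Package: distgan
Title: Adversarial Real-Valued Inter-Residue Distance Map Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for predicting real-valued protein inter-residue distance
    maps with a conditional generative adversarial network (cGAN). Provides the
    real-space/training-space mapping functions, assembly of 130-channel
    sequence-derived feature stacks, an effective-alignment-depth (Neff)
    statistic, a residual convolutional generator with Swish activation and a
    two-stage channel/pixel attention module, patch-classifier and
    spatial-pyramid-pooling discriminators with an analytic receptive-field
    calculator, the adversarial training loop with L1-regularised generator
    loss and clipped discriminator loss, CNS/CONFOLD-style distance-restraint
    export, a classical multidimensional-scaling embedder for geometric
    validation, and a synthetic-protein generator (backbones, conformational
    jitter ensembles, noisy feature bundles, toy alignments) so the whole
    pipeline runs at desk scale without external data. The small convolutional
    network engine (im2col convolution, batch normalisation, manual
    reverse-mode gradients, Adam) is implemented in the package with
    RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    tibble,
    generics,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
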