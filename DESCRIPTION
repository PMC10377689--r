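Package: midecode
Title: Subject-Independent Motor-Imagery EEG Decoding with CSP Features
    and a Dual-Branch Multiscale Autoencoder Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end subject-independent decoding of two-class motor-imagery
    EEG. Trials are band-pass filtered to the 8-30 Hz mu/beta range, projected
    through common spatial patterns (CSP), and summarised as spatial-spectral
    covariance images. A dual-branch convolutional network (a convolutional
    autoencoder branch and a multiscale convolution branch with additive latent
    fusion) classifies the images under a fused objective combining
    reconstruction error, cross-entropy and a center loss that promotes
    intra-class compactness. Includes a leave-one-subject-out evaluation
    harness, ablation variants of the network, a t-SNE feature visualiser, an
    HDF5 trial container, and a synthetic multi-subject EEG cohort generator
    with known class-dependent spatial structure for fully reproducible
    testing. The network layers (convolution, batch normalisation, pooling,
    transposed convolution, dense) and their gradients are implemented in the
    package with Rcpp kernels; no external deep-learning framework is used.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    Rtsne,
    jsonlite,
    signal,
    stats,
    grDevices,
    graphics,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
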