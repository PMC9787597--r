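Package: RamanForge
Title: Generative Augmentation of One-Dimensional Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Expands small sets of one-dimensional Raman spectra into large,
    diverse, realistic datasets. A handful of seed spectra are first augmented
    by random jittering (additive Gaussian noise) and horizontal shifting with
    zero fill, then used to train a one-dimensional Wasserstein generative
    adversarial network with weight clipping; a convolutional denoising
    autoencoder removes the amplified noise from generated spectra, and a
    zero-padding trick confines endpoint artifacts to disposable channels that
    are cut away after generation. Training can run centrally or by simulated
    federated averaging across decentralized nodes that never exchange raw
    spectra. Generated sets are scored by Frechet distance between fitted
    Gaussians, Pearson correlation, and Euclidean distance, and a synthetic
    Lorentzian/Gaussian peak spectrum simulator makes the whole system testable
    without proprietary chemical-agent data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
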