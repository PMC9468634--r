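Package: cryocssl
Title: Contrastive Self-Supervised Pretraining for Cryo-ET Subtomogram
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised representation learning for 3D cryo-electron
    tomography subtomograms. Implements momentum-contrast pretraining with a
    FIFO key queue and temperature-scaled InfoNCE loss, an in-batch
    (SimCLR-style) contrastive variant, a residual 3D convolutional encoder
    with gradient-weighted class activation mapping, a volumetric
    augmentation pipeline (random resized crop and random z-axis affine),
    and the semi-supervised fine-tuning protocol over label fractions with
    repeat statistics. Ships a synthetic subtomogram generator (parametric
    macromolecule motifs, crowded neighbourhoods, missing-wedge Fourier
    masking, calibrated signal-to-noise) so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
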