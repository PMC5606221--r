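Package: buds
Title: Bayesian Unidimensional Scaling for Latent Orderings from Dissimilarities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers latent one-dimensional coordinates for high-dimensional
    observations from pairwise dissimilarities. Dissimilarities are modeled as
    Gamma-distributed around shifted and scaled latent 1D distances, with
    data-driven heteroscedastic noise scales estimated from K-nearest-neighbor
    sets. Posteriors are approximated by mean-field automatic-differentiation
    variational inference (with a Metropolis fallback) and summarized as
    orientation-fixed point estimates with highest-posterior-density intervals.
    Downstream products include matrix seriation for reordered heatmaps,
    covariate association, smoothed feature-dynamics curves, principal
    coordinates and t-SNE embeddings with posterior trajectory paths, posterior
    dissimilarity cubes registered by three-way multidimensional scaling
    (DiSTATIS), and kernel-density clouds with per-observation confidence
    contours. A synthetic-data generator produces gradient-structured count,
    continuous and binary matrices with known orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
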