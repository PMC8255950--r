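Package: tomoprox
Title: Multichannel Variational Image Reconstruction by Proximal Splitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A block-operator framework for multichannel (colour, dynamic,
    hyperspectral) image restoration and tomographic reconstruction.
    Provides declarative image and acquisition geometries, multichannel
    containers with block algebra, a catalogue of linear maps (finite
    difference gradients with spatial or spatio-channel correlation,
    symmetrized gradient, masks, channelwise lifting, a ray-driven sparse
    projector) under one direct/adjoint contract, proper convex functions
    with proximal and conjugate-proximal maps, and first-order solvers:
    FISTA, primal-dual hybrid gradient (PDHG, explicit and implicit),
    stochastic PDHG with subset sampling, SIRT, CGLS, and filtered
    back-projection with a Ram-Lak filter.  Total variation, total
    generalized variation and directional total variation regularizers are
    included, together with synthetic phantom generators and end-to-end
    case-study pipelines for colour denoising/inpainting, sparse-view
    dynamic CT and hyperspectral K-edge CT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
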