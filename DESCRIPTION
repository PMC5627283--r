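Package: tractatlas
Title: Tractography Atlas-Based Analysis of Diffusion Tensor Images
Version: 0.1.0
Authors@R: person("TABS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Implements a tractography atlas-based analysis (TABS) pipeline
    for diffusion tensor imaging at desk scale: diffusion-tensor data
    structures with eigen-decomposition and scalar maps, scalar feature
    images (FA, Hessian-of-FA, T1-like) for driving registration, B-spline
    free-form deformation registration with groupwise mean-deformation
    normalization, sinusoidal ground-truth deformation simulation with
    tensor reorientation, a full tensor-similarity metric suite (OVL, DTED,
    DVED, AI, COH, corrFA), deterministic streamline tractography with
    arc-length tract parameterization, and along-tract group statistics
    using threshold-free cluster enhancement with permutation family-wise
    error control and ROC/AUC classification. A synthetic tensor phantom
    generator provides ground-truth bundles, per-subject anatomical
    variability, and configurable localized group effects, so the whole
    pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
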