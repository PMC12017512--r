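Package: msgrad
Title: Multiscale Structural Connectome Gradients and Developmental Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiscale structural connectome gradient analysis.
    Fuses geodesic distance, microstructural profile covariance, and
    tractography-derived tract strength into a single affinity matrix,
    embeds it with diffusion maps, and characterizes developmental change
    in the resulting gradients with penalized-spline mixed models
    (signed delta adjusted R-squared age effects). Includes
    variogram-matched spatially autocorrelated surrogate maps for
    autocorrelation-aware significance testing, structure-function
    coupling and participation-coefficient analyses, partial least
    squares correlation (PLSC) with permutation, bootstrap, and
    cross-validation, partial least squares regression (PLSR) against
    gene expression with surrogate-corrected enrichment, and a synthetic
    longitudinal cohort generator with planted gradient effects so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    tools,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
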