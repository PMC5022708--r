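Package: quantmat
Title: Evolutionary Quantitative Genetics on Trait Covariance Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of trait covariance and
    correlation matrices in evolutionary quantitative genetics: matrix
    estimation from individual-level data (fixed-effects residual and
    conjugate inverse-Wishart Bayesian), measurement-error repeatability,
    matrix repeatabilities via bootstrap, Monte Carlo and an analytic
    expression, Hansen-Houle selection-response statistics (evolvability,
    flexibility, respondability, conditional evolvability, autonomy,
    constraints), matrix comparison by random skewers, Mantel, Krzanowski
    subspace and eigenvalue-weighted PCA similarity, overlap and Riemannian
    matrix distances, selection-response decomposition, Riemannian
    (Frechet) mean matrices and eigentensor decomposition of matrix
    samples, variational-modularity tests and data-driven module search,
    drift tests against a neutral divergence null, phylogenetically
    structured matrix pooling, and synthetic-data generators for all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
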