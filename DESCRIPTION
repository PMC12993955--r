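Package: devqg
Title: Developmental Dynamical Systems for Quantitative Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links mechanistic models of development, written as ordinary
    differential equations, to the statistical machinery of quantitative
    genetics.  Computes time-resolved sensitivity vectors of developmental
    trajectories with respect to developmental parameters (by variational
    equations, finite differences, or regression on perturbed runs), relates
    them to average allelic effects, additive and dominance values, and
    estimates time-varying average effects from noisy developmental time
    series by per-time regression refined with a Kalman filter.  Builds
    additive-genetic (G), environmental (E) and phenotypic (P) covariance
    matrices from sensitivity vectors, quantifies their proportionality via
    leading-eigenvector angles, and simulates one generation of truncation
    selection with Mendelian inheritance to compare realized responses with
    multivariate breeder's-equation predictions.  Includes a two-gene
    bistable toggle-switch model and synthetic-population generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
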