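Package: miRKinet
Title: Kinetic Modeling and Single-Cell Inference of miRNA Target
    Repression Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models a network of mRNA targets competing for a limited pool
    of Ago-miRNA complexes, with closed-form steady states, deterministic
    (ODE) and stochastic (SSA / tau-leaping) simulation, a synthetic
    single-cell benchmark generator, and a rank-1 SVD procedure that infers
    per-cell free Ago-miRNA levels, per-target Michaelis-Menten constants
    (K_M) and critical free-Ago concentrations (A_F^C) from noisy
    cell-by-target expression matrices. Includes sliding-window single-cell
    statistics (coefficient of variation, pairwise correlations),
    CPM-normalization utilities for UMI count matrices, and deterministic
    ceRNA titration scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
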