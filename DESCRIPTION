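Package: remapgeom
Title: Population-Geometric Simulation and Analysis of Place-Field Remapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates hippocampal place-field remapping under the assumption of
    a linear decoder from population activity to a low-dimensional latent space.
    Environmental variables (position and cognitive features) are encoded as
    angles on a torus, mapped through environment-specific orthonormal embedding
    maps, and turned into nonnegative steady-state firing-rate maps by solving
    the spike-coding-network quadratic program. The package generates the three
    canonical remapping types (encoder-decoder, mixed-selective, null-space),
    quantifies remapping with population-vector overlap and spatial-correlation
    statistics against permutation shuffle nulls, decomposes remapping vectors
    into spatial, cognitive and null-space components, and provides angle-space
    tuning mosaics and gnomonic sphere projections for visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
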