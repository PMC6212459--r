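Package: gliomorph
Title: Individual-Cell-Based Simulation of Glioblastoma Spheroid Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid discrete-continuum, individual-cell-based simulator of
    glioblastoma spheroid invasion on a 2D exclusion lattice. Tumour cells
    proliferate with an age-based clock and quiescence, die under hypoxia
    governed by an oxygen reaction-diffusion field with Dirichlet boundaries,
    and perform adhesion-gated random walks: each cell carries an integer
    cell-to-cell adhesion preference (0-7) and only moves to empty Moore
    neighbours whose occupancy matches that preference. Heterogeneous mixtures
    of adhesion phenotypes alone reproduce distinct invasive morphologies
    (non-cohesive starburst versus cohesive sheet-like invasion). Includes
    spheroid morphometrics (core and invasive radii, local compactness and
    sparseness, phenotype frequencies, regression-based expansion speeds),
    synthetic phantom generators for validating the morphometrics, replicate
    ensembles, mitotic phenotype switching, and canned perturbation studies of
    proliferation and motility rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    withr,
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
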