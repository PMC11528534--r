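Package: paninsim
Title: Multiscale Simulation of Pancreatic Intraepithelial Neoplasia
Version: 0.1.0
Authors@R:
    person("paninsim", "developers", email = "paninsim@example.org",
           role = c("aut", "cre"))
Description: A multiscale model of the early stages of pancreatic ductal
    adenocarcinoma (PanIN 1 and PanIN 2). A 14-agent gene-regulatory
    network with Boolean logic is translated into delayed Hill-function
    differential equations driven by a Lotka-Volterra cytokine oscillator,
    and coupled to a two-dimensional Voronoi tissue with elastic vertex-model
    mechanics, finite-volume glucose transport on the cell adjacency graph,
    glucose-paced cell-cycle clocks that trigger division and death, and a
    tissue inflammation index with a duct-elongation relief mechanism.
    Includes exhaustive Boolean attractor analysis, scenario drivers for
    healthy tissue and graded cancer-cell seedings, and seeded fixture
    generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
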