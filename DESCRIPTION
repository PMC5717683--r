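Package: netforge
Title: Generation of Weighted Networks with Prescribed Spectral Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs symmetric, nonnegative, zero-diagonal weighted
    adjacency matrices whose spectral radius and whose dominant-eigenvector
    variance and skewness match user-supplied targets. The generator couples
    a bound-constrained quasi-Newton minimisation of a weighted
    sum-of-squares criterion (with analytic eigenvalue and eigenvector
    sensitivities) to a hill-climbing perturbation loop, subject to a linear
    equality-constraint system encoding zero diagonal, symmetry and forced
    disconnections. Includes closed-form feasibility bounds on the
    attainable eigenvector moments, convergence maps over target grids,
    readers and writers for square-matrix, edge-list and GraphML formats,
    and analytic fixture networks used as independent oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    xml2,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
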