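Package: shnet
Title: Swift-Hohenberg Pattern Formation on Complex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-species excitation dynamics on undirected graphs with
    short-range inhibitory and longer-range diffusive coupling, a network
    analogue of the Swift-Hohenberg model. Provides graph generators and
    readers, Laplacian and bi-Laplacian coupling operators with their shared
    spectral decomposition, flat-state and normal-mode linear stability
    analysis, semi-implicit time integration and Newton steady-state solving,
    pseudo-arclength continuation of homoclinic-snaking branches of localized
    "quantized" states, stimulus-robustness experiments, and a degree-based
    mean-field approximation of global Turing patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
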