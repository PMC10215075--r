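Package: mcfrw
Title: Random-Walk Model of Water Diffusion in the Mineralized Collagen Fibril
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a staggered, randomly perturbed collagen-apatite obstacle
    model of the mineralized collagen fibril (MCF), simulates obstructed
    Gaussian random walks of water particles through it, and analyses the
    resulting trajectories: time-averaged mean squared displacement, linear
    MSD fits and Einstein-relation diffusion coefficients, path tortuosity,
    and first-passage sub-trajectory statistics at reference planes along the
    fibril axis. Includes analytic test fixtures, brute-force oracles, a
    reproducible pipeline driver and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
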