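Package: spikefield
Title: Spiking Dynamic Neural Field Simulation with Short-Range
    Mexican-Hat Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a two-dimensional lattice of conductance-based
    integrate-and-fire neurons coupled through a difference-of-Gaussians
    (Mexican hat) lateral kernel with short-range inhibition, as used to
    model target selection in topographic visual structures such as the
    superficial superior colliculus. Provides deterministic rate-driven
    stimulus generators (lines, squares, disks, competing point pairs),
    a fast compiled lattice integrator with an independent brute-force
    reference engine, spiking-cluster detection and localization metrics
    (counts, centers of gravity, deviations, latencies, rise speeds,
    steady firing rates), and drivers for the full size-sweep and
    two-stimulus competition protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
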