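Package: organoidsim
Title: Discrete-Event Simulation of Neural Tissue Development on a 3D Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An agent-based, discrete-event simulator of neural tissue
    development on a three-dimensional integer lattice with Chebyshev
    geometry. Cells are logical objects whose behaviour is attached
    exclusively through predicate-guarded signaling pathways that
    parametrize a fixed set of built-in mechanisms: morphogen secretion
    and diffusion (truncated discrete-Gaussian convolution), signal
    transduction, gradient-following locomotion and A* pathfinding,
    symmetric and asymmetric division, lineage-restricted
    differentiation, apoptosis and necrosis, axon growth-cone guidance,
    and a factor-mediated synaptogenesis handshake. Ships with
    scale-parameterized organoid configurations that grow a layered,
    synaptically connected structure from a single stem cell, and an
    analysis layer for census dynamics, radial layer distributions,
    connectivity rates and axon-length statistics. Runs are fully
    reproducible for a fixed configuration and seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
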