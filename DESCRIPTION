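Package: vesiflow
Title: Multiscale Simulation of Reaction-Diffusion and Vesicle Trafficking in Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid simulation framework for cellular signalling systems that
    couples a compartmentalised two-dimensional reaction-diffusion grid with
    agent-based vesicle dynamics under a shared adaptive-time-step error
    controller. Chemical species are represented as graphs of simple entities
    joined at declared binding sites, and full mass-action reaction networks
    are generated from rule-based reactor chains (add, bind, remove, release).
    Vesicles, filaments, membranes and volume regions are first-class agents
    with Brownian and filament-guided transport, stochastic state changes,
    clathrin-mediated endocytosis with a cargo checkpoint, and SNARE-gated
    fusion. Ships runnable configurations of a PKA/AQP2 signalosome:
    an allosteric PKA phosphorylation model, a cAMP compartmentalisation
    model, a clathrin-mediated endocytosis model, and a full aquaporin-2
    recycling model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    generics,
    rlang,
    png,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
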