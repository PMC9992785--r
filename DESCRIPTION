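Package: seafloorenergy
Title: Energy Fluxes Across the Seafloor: Cementation, Transport, and Bioturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: An order-of-magnitude energy-balance framework for carbonate
    seafloor cohesion. Computes three competing area-normalized energy
    fluxes: the loss of crystal-fluid interfacial free energy during
    carbonate cementation, the kinetic energy delivered to the bed by
    saltating and suspended grains during sediment transport, and the
    mechanical work done by burrowing animals (gravitational excavation
    and crack-propagation end members). Builds ratio maps over grain-size
    by shear-velocity grids, quiet-water flux comparisons from
    population-level sediment-reworking tables, and substrate-stability
    scenario algebra for perturbations to porewater chemistry, benthic
    biomass, and body size.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readxl
Config/testthat/edition: 3
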