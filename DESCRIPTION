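Package: fluxmapr
Title: Flux Maps on Bipartite Metabolic Networks: Import, Balance
    Validation and Rendering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Imports structured flux datasets (conditions, time points,
    substance weights, reaction equations, flux values with optional
    quality parameters), maps them onto bipartite metabolite-reaction
    networks, validates reaction- and metabolite-level flux balances
    (atom conservation for substance fluxes such as 13C carbon maps,
    with the mass-flux special case of unit weights), and renders flux
    maps as SVG/PNG with edge thickness proportional to flux, dashed
    zero-flux edges and red colour graduation for quality values.
    Includes hub-node splitting with label reconnection overlays, a
    deterministic layered layout with optional Graphviz DOT delegation,
    SBML/GML/SIF import, GML/GraphML export, and a deterministic
    generator of balanced and deliberately corrupted synthetic flux
    datasets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    jsonlite,
    readxl,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
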