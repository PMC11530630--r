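Package: microflow
Title: Modular 1D Lumped-Element Simulation of Pressure-Driven
    Microfluidic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven one-dimensional simulation of pressure-driven
    microfluidic chip networks using the hydraulic-electric circuit
    analogy.  Rectangular channels are lumped into hydraulic resistances,
    node pressures and channel flow rates are solved by Modified Nodal
    Analysis, and plug-flow transport of miscible mixtures is tracked by
    exact interface advection between discrete events.  Optional modules
    add flow-rate-weighted mixing at junctions, droplet routing with
    droplet-resistance coupling, and diffusive species exchange between a
    channel and a membrane-coupled tank (an organ-on-chip abstraction)
    integrated with the classic fourth-order Runge-Kutta scheme.
    Networks are described in a JSON dialect with optional units;
    programmatic fixture generators cover gradient-generator trees,
    droplet ring networks, and membrane test channels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
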