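Package: papm
Title: IP3 Diffusion and Molecule Counts in a Perisynaptic Astrocyte Projection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Order-of-magnitude analysis of inositol 1,4,5-trisphosphate (IP3)
    diffusion inside an idealized cylindrical peri-synaptic astrocyte
    projection (PAP). Provides the analytical eigenfunction solution of the
    1-D transient diffusion equation with a constant-concentration source at
    one end and a no-flux wall at the other, conversions between molar
    concentration and absolute molecule number at femtoliter-and-below
    volumes, a phospholipase C (PLC) synthesis budget capped by the PIP2
    cluster pool, integer-molecule allocation profiles along the projection,
    and back-of-envelope IP3 receptor capacity estimates at the Ca2+ store
    face. Independent finite-difference and stochastic particle oracles
    validate the analytical solution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
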