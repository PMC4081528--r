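Package: cochperm
Title: Water Permeability of the Cochlear Perilymph-Endolymph Barrier
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compartmental modelling toolkit for water exchange across the
    cochlear duct epithelium. Computes perilymph-endolymph barrier surface
    areas from half-turn morphometry tables, simulates one-dimensional tracer
    dispersal in the three coupled cochlear scalae (diffusion, perfusion
    advection, first-order scala-scala and scala-blood exchange), fits the
    two-exponential endolymphatic uptake model to extract exchange rate
    constants, and derives diffusional (P_D) and osmotic (P_f) water
    permeability coefficients, their ratios, and aquaporin channel-density
    estimates with strict unit handling. Includes a seeded synthetic-data
    generator for every input class so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
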