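Package: axonzipper
Title: Biophysics of Axon Shaft Zippering and Fasciculation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the biophysical analysis of axon shaft zippering in
    developing neural networks. Implements the static force balance between
    axon mechanical tension and axon-axon adhesion at a zipper vertex, an
    overdamped equation of motion for the vertex on the tension/adhesion
    energy landscape with elongation, vertex-localized and substrate
    friction, Biomembrane Force Probe (BFP) analysis for axon tension
    estimation, change-of-variables inference of the adhesion force from
    tension and angle distributions, coarsening statistics of segmented
    planar axon networks, and seeded synthetic-data generators emulating the
    microscopy and probe recordings that the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
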