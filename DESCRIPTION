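Package: magtensio
Title: Magnetic Force Tensiometry of Multicellular Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for magnetic force tensiometry of
    nanoparticle-labelled multicellular spheroids. Integrates the
    axisymmetric Young-Laplace equation under a uniform volumetric magnetic
    force (Bashforth-Adams form) to predict equilibrium flattened-drop
    profiles, inverts the model by quadratic-error minimization on profile
    landmarks (height, width, volume) to recover tissue surface tension,
    derives the Young's modulus from the contact-zone radius via Hertz
    contact theory, decomposes tissue surface tension into cell-medium
    cortical tension and effective cell-cell tension from junction contact
    angles, quantifies cryosection contour roughness about a least-squares
    circular arc, and fits unconstrained four-parameter Hill dose-response
    curves with IC50 extraction. Seeded synthetic-fixture generators
    emulate the experimental regime so every stage is testable without
    image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
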