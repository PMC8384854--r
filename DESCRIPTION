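Package: conchmorph
Title: Geometric Morphometrics of Nautilid Conch Ontogeny
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-dimensional geometric morphometrics of chambered
    cephalopod conchs through ontogeny: equidistant landmarking of suture
    lines and whorl cross-sections, sliding semi-landmarks by thin-plate
    spline bending-energy minimization, generalized Procrustes analysis,
    principal components of shape, neighbor-joining similarity trees at
    defined ontogenetic stages, and stage-stratified septal-spacing
    statistics. Includes a parametric synthetic-conch generator
    (logarithmic-spiral coiling, harmonic whorl outlines, lobed sutures,
    hatching and crowding signals in septal spacing) so the whole pipeline
    runs and is testable without CT data, and TPS/CSV/Newick interfaces so
    real landmark data can replace the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
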