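Package: mtarrival
Title: Brownian-Dynamics Simulation of Protein Arrival at Microtubule Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-molecule Brownian-dynamics simulation of diffusion-limited
    arrival of a microtubule-binding protein at structured microtubule
    lattices.  A pocket-binding molecule (such as the EB1 calponin-homology
    domain, which docks in the vertex between four tubulin dimers) or a
    face-binding molecule (such as a kinesin motor domain) diffuses
    translationally and rotationally with Stokes-Einstein coefficients,
    collides with a convex-polyhedron model of the tubulin lattice, and is
    captured when its binding interface is stereospecifically registered
    with a binding site.  The package builds blunt, tapered, open-sheet and
    single-dimer lattice geometries, enumerates and classifies binding sites
    by the number of adjacent dimers, aggregates arrival statistics, and
    provides the accompanying fluorescence quantification procedures:
    error-function fitting of tapered tip profiles, intensity-ratio and
    coverage metrics, comet occupancy profiles, and censored-exponential
    dwell-time and on-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
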