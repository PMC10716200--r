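Package: helixvessel
Title: Biomechanics of Externally Helix-Reinforced Vascular Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of decellularized vascular scaffolds
    externally reinforced with extruded polymer helices (PVDF or PCL).
    Generates idealized cylindrical scaffold geometry with heterogeneous
    wall thickness and double-helix reinforcement paths, implements a
    damage-coupled elastoplastic constitutive law for the biological wall
    (modulus degradation driven by accumulated plastic strain), solves
    quasi-static internal-pressure equilibrium on a reduced thin-shell
    model, and drives cyclic-pressure aneurysm-growth simulations and
    virtual compliance and tension experiments comparing unreinforced and
    reinforced vessels. Reads and writes STL surface meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
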