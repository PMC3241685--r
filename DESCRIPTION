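Package: elbamd
Title: Coarse-Grained Molecular Dynamics of Lipid Membranes with the
    ELBA Force Field
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Self-contained coarse-grained molecular dynamics for lipid
    membranes with the electrostatics-based (ELBA) force field: a
    single-site dipolar (Stockmayer) water model, 15-site
    phosphatidylcholine and phosphatidylethanolamine lipids carrying
    explicit point charges and point dipoles, shifted-force truncated
    nonbonded interactions, a coupled translational/rotational
    velocity-Verlet integrator with weak-coupling temperature and
    pressure control, and the standard membrane observables: electron
    density and lateral pressure profiles, curvature elastic moments,
    transmembrane electrostatic potential, tail order parameters,
    lateral diffusion and water permeability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
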