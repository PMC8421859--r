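Package: cgcam
Title: Coarse-Grained Community Modeling of Calcium-Calmodulin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Three-bead coarse-grained modeling of calcium-loaded calmodulin
    with a segmented, weighted fragment-memory potential and an implicit
    calcium charge model built on EF-hand coordination chemistry. Includes
    the physics-based force-field terms (backbone geometry, contact, burial
    and hydrogen-bond potentials of mean force, Debye-Hueckel
    electrostatics), Langevin dynamics with simulated annealing and
    radius-of-gyration umbrella sampling, and the analysis stack (radius of
    gyration, Qw structural similarity, MBAR/WHAM free-energy profiles, and
    collapsed-to-extended population ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
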