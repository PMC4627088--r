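Package: cgsearch
Title: Coarse-Grained Simulation of Protein Target Search on Confined DNA
Version: 0.1.0
Authors@R:
    person("Anonymous", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin dynamics of a C-alpha Go-model
    DNA-binding protein searching a three-bead-per-nucleotide (3SPN-style)
    DNA duplex. Includes Debye-Huckel phosphate electrostatics, a
    cylindrical caging potential that mimics macromolecular crowding,
    an ideal B-DNA builder calibrated against rigid groove widths, a
    trajectory analysis suite (sliding/hopping/3D search-mode
    classification, groove geometry and occupancy, rotation-coupling,
    sliding-event statistics, 1D diffusion coefficients) and a
    specific-binding kinetics ensemble driven by the fraction of
    specific contacts Q_sp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
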