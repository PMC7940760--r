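Package: rest2tools
Title: Replica Exchange with Solute Tempering and Peptide-Protein
    Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machinery for replica exchange with solute tempering (REST2)
    on decomposable Hamiltonians, together with an analysis pipeline for
    peptide-protein trajectories: Kabsch-Sander secondary-structure
    assignment, RMSD conformational clustering with the gromos
    neighbour-count algorithm, density-based binding-pose clustering,
    heavy-atom contact maps, binding propensities, salt bridges and
    hydrogen bonds. Includes a synthetic-trajectory generator that plants
    beta-hairpins, binding poses and salt bridges with ground-truth labels
    for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
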