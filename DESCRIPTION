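Package: lssr
Title: Local Structural Similarity Restraints for Macromolecular Models
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates local structural similarity restraints
    (LSSR): plateauing penalties on differences between equivalent short-range
    interatomic distances, used to exploit noncrystallographic symmetry (NCS)
    or similarity to a fixed target structure during macromolecular model
    refinement. Provides PDB and mmCIF coordinate input, automatic NCS chain
    detection, restraint-list construction with bonded-pair exclusion,
    analytic gradients, plateau-ratio and gradient-based restraint pruning,
    equivalent side-chain atom swapping, distance-difference diagnostics, a
    synthetic fixture generator with a toy restrained minimizer, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
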