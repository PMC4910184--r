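Package: marrowsim
Title: Deterministic Cellular-Automaton Model of Bone Marrow Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates hematopoietic stem cell dynamics in the bone marrow as
    a deterministic cellular automaton on a two-dimensional Moore lattice.
    Stem cells proliferate into empty space by a directional round-robin rule,
    convert to transit-amplifying (transitive) cells when saturated by stem
    neighbours, become quiescent, and undergo apoptosis after a fixed number
    of renewals; transitive cells mature through generations, differentiate,
    and can dedifferentiate back to stem cells after severe perturbations.
    The package provides scenario builders, per-step metrics (stem density,
    quiescent fraction, differentiated-cell output), state classification
    (death, dying-out, resonant states) with cycle detection, and verifiers
    for the model's provable homeostasis bounds (stem occupation time, stem
    density, differentiated-cell supply).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
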