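Package: excidock
Title: Blind Docking of Formulation Excipients to Map Protein Interaction Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Screens formulation excipients (sugars, amino acids, polyols,
    surfactants) against a whole protein surface by blind flexible docking
    with an empirical interaction score, docks two protein copies with a
    softened Lennard-Jones rigid-body search, consolidates the resulting
    poses into residue-level interaction hotspots, tests hotspot overlap
    with predicted protein-protein interfaces, validates contacts against
    multi-model trajectories, and correlates per-excipient mean binding
    affinity with experimental melting temperatures. Includes deterministic
    toy-structure generators so the whole pipeline runs without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
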