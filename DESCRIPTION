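Package: hotforge
Title: Physics-Based Interface Hotspot Mapping and Design-Ensemble Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps energetic hotspots on protein-protein interfaces from PDB
    coordinates using inter-chain Lennard-Jones and screened Coulomb pair
    energies under an embedded ff14SB-derived nonbonded parameter subset,
    with a hydrogen-charge folding scheme for heavy-atom-only structures.
    Builds chain-aware Calpha distance, reciprocal-distance and binary
    contact maps; benchmarks per-residue hotspot rankings against external
    contact-energy tables (Spearman, Pearson, Top-N overlap, Jaccard,
    recall); and triages design ensembles with confidence filtering,
    Kabsch-superposed per-residue backbone RMSD profiles, energy-distance
    regression, Needleman-Wunsch alignment, normalized Hamming distances
    and per-column Shannon entropy. Includes seeded generators for
    synthetic two-chain helical complexes, mock contact tables, mock
    design-metrics tables and mutated sequence ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    graphics,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
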