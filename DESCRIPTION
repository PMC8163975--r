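Package: raseffector
Title: RAS-Effector Interface Contacts, Hotspots and Binding-Affinity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of RAS GTPase interactions with RA/RB effector domains:
    extracts intermolecular residue contacts (4 Angstrom heavy-atom cutoff)
    from two-chain complex structures, projects them through multiple sequence
    alignments onto reference numbering (HRAS on the GTPase side, CRAF/RASSF5
    on the effector side), aggregates them into a per-complex-support
    interaction matrix, calls binding hotspots, designs hotspot residue-swap
    variants, and fits fluorescence-polarization titrations with the quadratic
    ligand-depletion binding model to classify dissociation constants into
    affinity bands. Includes a synthetic-data generator (toy complexes with
    planted contacts, alignments with planted conservation, simulated
    titrations) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
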