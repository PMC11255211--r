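Package: altlocr
Title: Mining Alternately Located Backbone Conformations from Protein
    Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts and characterizes alternate atomic locations
    (altlocs) from protein crystal structure files. Parses PDB-format
    coordinates into per-chain residue/atom tables, canonicalizes altloc
    labels, computes backbone dihedral angles per alternate conformation,
    converts isotropic B-factors to positional standard deviations,
    measures raw and uncertainty-normalized inter-conformer alpha-carbon
    distances, detects and classifies sub-threshold atomic contacts,
    assigns codons by aligning translated coding sequences, filters
    structures by R-factor quality criteria with a resolution-dependent
    cutoff, clusters chains into non-redundant sequence families, groups
    contiguous altloc-harboring residues into segments, and emits
    per-residue and per-chain CSV tables with a fixed published-style
    schema. Includes a synthetic-structure generator with planted ground
    truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr
Config/testthat/edition: 3
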