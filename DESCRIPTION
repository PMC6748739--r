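Package: contactarea
Title: Direct Interatomic Contact Surface Areas by Extended Shrake-Rupley Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Direct calculation of interatomic contact surface areas (CSA) for
    molecular structures and complexes with an extended Shrake-Rupley point
    sampling algorithm.  Instead of discarding surface points buried by
    neighbouring atoms, the engine records the full set of occluding atoms for
    every buried point and attributes shared surface patches fractionally, so
    that contact areas account for the shielding effects of neighbouring
    atoms.  Also computes solvent accessible surface areas (SASA), buried
    surface areas (BSA), and the classical differential-SASA approximation of
    interface area for comparison.  Reads Protein Databank (PDB) and Tripos
    Mol2 files, auto-detects molecular objects (protein, nucleic acid,
    ligand), writes tab-separated contact matrices and B-factor-annotated PDB
    files, renders contact-map images, and ships a command-line interface with
    five modes of operation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    optparse,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
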