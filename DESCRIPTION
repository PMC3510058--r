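Package: aggkin
Title: Aggregation Kinetics of Coarse-Grained Amyloid Peptide Assemblies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the onset of amyloid aggregation in
    coarse-grained multi-peptide simulations. Detects beta-sheet clusters
    from DSSP-style hydrogen bonds and backbone dihedral criteria, tracks
    cluster lineages between frames to classify kinetic events (monomer
    addition/loss, oligomer fusion/fragmentation, direct monomer-oligomer
    interconversion), computes per-size creation/destruction rates and
    event totals, extracts free-energy profiles over aggregate size and
    beta-residue count with critical-nucleus determination, and fits a
    classical nucleation theory model. Ships a synthetic-data module
    (idealized beta-sheets, random-coil boxes, scripted trajectories with
    ground-truth events, and an exact Gillespie aggregation simulator with
    a detailed-balance mode) so the full pipeline is testable without
    molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    data.table,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
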