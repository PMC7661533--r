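Package: icocapsid
Title: Geometry, Symmetry and Interface Analysis of Icosahedral Virus Capsids
Version: 0.1.0
Authors@R:
    person("Capsid", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the comparative structural analysis of icosahedral
    virus capsids from atomic models: reading and writing PDB/mmCIF
    coordinate files, generation of the 60-element icosahedral rotation
    group and symmetry expansion of an asymmetric unit, radial shell
    profiling with inner/outer diameter and inner-volume estimation
    (sphere model and voxel flood-fill cross-check), packaging density as
    capsid volume per genome nucleotide, native Shrake-Rupley solvent
    accessible surface area with buried-surface-area interface analysis,
    residue contact networks around symmetry axes, polyprotein cleavage
    arithmetic, and a seeded synthetic-capsid generator so the whole
    pipeline is testable without any structure downloads.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
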