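Package: crossbeta
Title: Modeling and Analysis of Heteromeric Amyloid Fibril Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling axial-stacking cross-interactions between
    amyloid fibrils of two different peptides (the amyloid-beta / islet
    amyloid polypeptide junction as the worked case). Provides template-pair
    selection by gapless residue correspondence and backbone Kabsch
    superposition, generation of beta-sheet-like harmonic Ca:Ca distance
    restraints and graded shape-similarity restraint schedules, a
    coarse-grained restrained minimization and Langevin dynamics engine to
    drive junction formation, and trajectory analyses: hydrogen-bond
    occupancy and contact-probability maps, beta-sheet content, quality
    threshold clustering, RMSD series, polymorph comparison, and
    residue-pairwise polar/nonpolar interaction energy maps under a
    generalized Born surrogate solvent model. A synthetic-fixture generator
    builds idealized parallel in-register cross-beta fibrils so the whole
    pipeline runs without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
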