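Package: vestidock
Title: Virtual Screening of Peptide Toxin Block of Inward Rectifier
    Potassium Channels
Version: 0.1.0
Authors@R:
    person("Vestidock", "Developers", email = "vestidock@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for modelling peptide-toxin block of
    inwardly rectifying potassium (Kir) channels. Builds chimeric channel
    subunits by splicing an outer-vestibule sequence onto a fixed crystal
    template backbone ("limited" homology modelling), assembles C4
    tetramers from template-derived symmetry operators, performs
    grid-based rigid-body docking of peptide conformer ensembles with an
    FFT translational scan and a composite shape/electrostatic/contact
    score, clusters top poses by ligand C-alpha RMSD (greedy clustering),
    analyses the docked interface (solvent accessibility, footprint
    classes, hydrogen bonds, salt bridges, contact rings), and drives an
    in silico site-directed mutagenesis screen to rank vestibule
    hotspots. Ships a deterministic synthetic-structure generator so the
    whole pipeline is testable with no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
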