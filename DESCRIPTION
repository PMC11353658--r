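Package: pepsilico
Title: In Silico Discovery and Profiling of Food-Derived Bioactive Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for in silico discovery of bioactive
    peptides from food proteins. Performs virtual proteolysis of protein
    sequences with named protease specificities, computes the theoretical
    degree of hydrolysis and BIOPEP-style release-frequency statistics (AE
    and W) against a bioactive-peptide motif database, profiles peptides and
    proteins with ProtParam-style physicochemical descriptors (masses,
    isoelectric point, GRAVY, aliphatic and instability indices), evaluates
    Lipinski rule-of-five drug-likeness from sequence-derived descriptors
    (molecular formula, hydrogen-bond donors and acceptors, additive logP and
    TPSA estimates), and scores protein-peptide complexes with a
    contact-based binding-affinity model (interfacial contacts,
    non-interacting surface, dissociation-constant conversion and
    stage-weighted docking score combination). Includes a seeded synthetic
    data generator for proteins, motif databases and toy complexes with
    known interface ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
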