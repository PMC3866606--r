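Package: sprotannot
Title: Structure-Based Functional Annotation of Small Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for evolution/structure-based annotation of
    small proteins (50-100 residues): model quality assessment (secondary
    structure, hydrogen-bond pattern, Ramachandran stereochemistry, confidence
    tiers), structural classification by TM-score nearest neighbour with
    CATH-style fold-label transfer, template-based protein-protein interaction
    inference with a knowledge-based contact potential and Gaussian p-value
    calibration, and template-transfer prediction of ligand and metal binding
    sites with fingerprint virtual screening. Ships seeded synthetic generators
    that emulate the external structure, proteome and compound libraries so
    every stage runs and is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
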