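Package: fieldQSAR
Title: CoMFA/CoMSIA Molecular-Field QSAR with PLS and External Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 3D-QSAR pipeline for small-molecule agonist series:
    structure construction from scaffold/substituent tables, MMFF94
    conformer generation and Gasteiger charging via Open Babel, rigid
    alignment onto a template by common-substructure least squares,
    CoMFA (Lennard-Jones / Coulomb) and CoMSIA (Gaussian similarity
    index) grid fields, column-filtered NIPALS partial least squares
    with leave-one-out cross-validation, internal and external
    (Golbraikh-Tropsha) validation statistics, and STDEV*COEFF contour
    field export in OpenDX format. Ships the dibenzazepine /
    dibenzoxazepine TRPA1 agonist dataset used throughout the
    documentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, igraph, ChemmineR
SystemRequirements: Open Babel (obabel on PATH)
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
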