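Package: RNAStructStats
Title: Statistical Descriptors of RNA Tertiary Structures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes global size and shape descriptors (radius of gyration,
    gyration-tensor eigenvalues, asphericity and shape parameter), base-local
    reference frames with cylindrical base-pair and base-stacking geometry,
    secondary-structure motif statistics (canonical and non-canonical pairs,
    stems, hairpin/bulge/internal/junction loops, pseudoknot resolution), and
    atom-type-pair distance distributions for RNA 3D structures read from
    mmCIF or legacy PDB coordinate files. Dataset-level aggregation includes
    Flory-type power-law fits of size versus length, linear base-pair-count
    fits, and per-pair-class Gaussian geometry fits. Synthetic helix, hairpin
    and point-cloud generators with machine-readable ground truth make every
    component testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralBioinformatics, DataImport, Sequencing
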