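Package: ptomap
Title: Single-Molecule Optical Mapping of DNA Phosphorothioate Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and measurement pipeline for single-molecule
    optical mapping of DNA phosphorothioate (PT) epigenetic modifications.
    Scans genomes for PT consensus motifs (single-stranded and bistranded),
    simulates partially modified DNA molecules passing through the two
    labeling chemistries (iodine nick conversion with fluorescent fill-in,
    including double-strand-break artifacts, and covalent quantum-dot
    labeling), models molecular combing and diffraction-limited spot
    collapse, and implements the measurement procedure used on combed
    molecules: lambda-standard calibration of the micrometre-to-kilobase
    conversion, end-label orientation, molecule selection, neighbor-spacing
    statistics, molecule-to-molecule heterogeneity metrics, and a
    shifted-exponential occupancy-density estimator with bootstrap
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, rtracklayer, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
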