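Package: CondensateKit
Title: Quantification of Protein-DNA Condensation from Single-Molecule and
    Condensate Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify heterochromatin protein 1 (HP1) driven DNA
    condensation from microscopy and force spectroscopy data: kymogram
    construction and DNA-end tracking on DNA curtains with compaction-rate
    fitting; fluorescence-conservation and association-rate analysis that
    discriminates equal versus blocked protein binding to compacted DNA;
    multi-scale Canny segmentation of brightfield condensates with
    complementary-cumulative-distribution radius statistics, bootstrap
    confidence bands and power-law fits versus concentration; line and
    whole-droplet FRAP analysis with biexponential recovery fitting and a
    spatially varying photobleach correction; and worm-like-chain
    force-extension analysis including the energy barrier between curves.
    Seeded synthetic-data generators emulate every input so each estimator
    is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    signal,
    minpack.lm,
    pracma,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, SingleMolecule
RoxygenNote: 7.3.3
Collate:
    'CondensateKit-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthetic-kymogram.R'
    'synthetic-droplets.R'
    'synthetic-frap.R'
    'synthetic-force.R'
    'curtain-tracking.R'
    'binding-kinetics.R'
    'canny.R'
    'droplet-morphology.R'
    'frap-analysis.R'
    'force-analysis.R'
    'io.R'
    'pipeline.R'
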