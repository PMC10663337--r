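Package: chromfold
Title: Analysis of 3D Chromatin Domain Folding from FISH Distances, 5C
    Matrices, and Restraint-Model Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the three-dimensional folding of regulatory
    chromatin domains. Implements the three-loci survival-zone method, which
    inverts population distributions of pairwise 3D DNA FISH distances among
    three coplanar loci into the radii of the disks each locus explores, the
    angle between locus axes, and constrained per-nucleus positions.
    Provides post-alignment 5C contact-matrix processing (primer z-score
    filtering, read scaling, overlapping binning, Sinkhorn-Knopp/ICE
    balancing, LOWESS expected-by-distance, and anchored-window interaction
    quantification), contact-arch and differential-arch analysis of 3D
    bead-chain model ensembles, inter-probe FISH distance statistics with
    exact tests, the RNA polymerase II pausing index, and a synthetic-data
    generator that emulates the statistical structure of all these inputs
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
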