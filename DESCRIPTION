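Package: zedscape
Title: H2A.Z Chromatin Landscapes and Histone Modification Stoichiometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the chromatin landscape of the histone
    variant H2A.Z and the stoichiometry of its post-translational
    modifications. The genomics arm calls genome-wide enriched intervals
    from aligned ChIP-Seq reads using sliding-window counting against a
    randomised-read background, classifies promoters into chromatin states
    (H3K4me3-only, bivalent, H3K27me3-only, no-mark), builds TSS-anchored
    signal matrices and class- or expression-quartile-stratified composite
    profiles, and computes interval-overlap statistics including intergenic
    multiple transcription-factor binding locus (MTL) occupancy. The mass
    spectrometry arm quantifies positional isomers of C-terminal
    ubiquitination from extracted ion chromatograms, precursor-level
    acetyl stoichiometry, b-ion based monoacetyl site localisation, and
    diacetyl positional-isomer mixtures by constrained least squares.
    A seeded synthetic-data generator with exported ground truth makes
    every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
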