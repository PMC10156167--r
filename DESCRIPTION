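Package: screenkit
Title: Analysis of Single-Cell CRISPRi Enhancer Screens Along a
    Differentiation Trajectory
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled single-cell CRISPRi screens read out by
    droplet RNA sequencing during a differentiation time course, with an
    emphasis on enhancer perturbations in cardiomyocyte differentiation.
    Implements saturation-curve (knee point) assignment of sgRNAs and
    hashing antibodies to cells, quality filtration of guides against the
    non-targeting background via a combination/cutoff hypergeometric
    procedure, hypergeometric enrichment and depletion tests of perturbed
    cells across trajectory states, Mann-Whitney pseudotime-shift tests,
    resampling Z-tests on state-defining gene sets, candidate enhancer
    prioritization from ATAC peaks and H3K27ac enrichment, and a fully
    specified synthetic-screen generator so that every stage can be
    exercised and validated without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
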