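Package: phageTnScreen
Title: Simulation and Analysis of Transposon Insertion Sequencing Phage
    Selection Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for transposon-directed insertion site sequencing
    (TraDIS) screens that select a saturating Tn5 mutant library with
    lytic bacteriophage. Provides a generative simulator of annotated
    genomes, saturating insertion libraries, phage selection and tagged
    single-end reads with known ground truth; transposon-tag
    verification, exact-match junction mapping and per-sample insertion
    profiles; gene-level read and insertion-site counting with
    library-saturation statistics and unassayable-gene flagging; exact
    conditional binomial tests of per-gene count changes with log
    counts-per-million fold changes and Benjamini-Hochberg false
    discovery control; consensus susceptibility/resistance calls across
    replicate selections; and ordinal scoring of plaque-assay lysis
    profiles against predicted phenotype directions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate:
    'phageTnScreen-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'simlib.R'
    'tagproc.R'
    'quant.R'
    'diffstats.R'
    'consensus.R'
    'phenotyping.R'
    'io.R'
    'screen.R'
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Transcriptomics, FunctionalGenomics, Software
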