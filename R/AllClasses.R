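#' Simulation configuration for a transposon-library phage screen
#'
#' `SimConfig` collects the generative parameters of the simulator: genome
#' layout, library saturation, read geometry and sequencing depth. Defaults
#' reproduce the screen design this package models: a saturating Tn5 library
#' with one insertion per 47 bp on average, 50-bp single-end reads whose
#' first 10 bp are transposon sequence, and four replicate selections
#' (two phage doses at two exposure times) alongside an untreated control.
#'
#' @slot nGenes number of genes laid out on the genome.
#' @slot geneLength length of each gene in bp.
#' @slot intergenicLength length of each intergenic block in bp; blocks
#'   alternate with genes and flank the whole layout, so the genome is
#'   `(nGenes + 1) * intergenicLength + nGenes * geneLength` bp.
#' @slot essentialFraction fraction of genes flagged essential; the first
#'   `ceiling(nGenes * essentialFraction)` genes are essential
#'   (deterministic assignment), and essential genes reject all insertions.
#' @slot insertionDensity mean bp per insertion site (47 for a saturating
#'   Tn5 library).
#' @slot readLength single-end read length in bp (50).
#' @slot tagLength length of the transposon tag at the read start (10).
#' @slot tagSequence the tag itself; default is the first 10 bp of the Tn5
#'   mosaic end.
#' @slot depthPerSample reads sequenced per sample.
#' @slot generations effective selection generations for each replicate
#'   selection; dose and exposure time both scale kill-off, so the four
#'   replicates (low/high dose x 3 h/5 h) are encoded as four values.
#' @slot seed base RNG seed; identical config and seed give byte-identical
#'   output.
#'
#' @seealso [simConfig()], [simulateGenome()], [simulateScreen()]
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer",
    geneLength = "integer",
    intergenicLength = "integer",
    essentialFraction = "numeric",
    insertionDensity = "numeric",
    readLength = "integer",
    tagLength = "integer",
    tagSequence = "character",
    depthPerSample = "integer",
    generations = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
  if (object@geneLength <= 0L) msg <- c(msg, "geneLength must be > 0")
  if (object@intergenicLength <= 0L)
    msg <- c(msg, "intergenicLength must be > 0")
  if (object@essentialFraction < 0 || object@essentialFraction > 1)
    msg <- c(msg, "essentialFraction must be in [0, 1]")
  if (object@insertionDensity <= 0)
    msg <- c(msg, "insertionDensity must be > 0")
  if (object@readLength <= 0L) msg <- c(msg, "readLength must be > 0")
  if (object@tagLength < 1L) msg <- c(msg, "tagLength must be >= 1")
  if (object@tagLength >= object@readLength)
    msg <- c(msg, "tagLength must be smaller than readLength")
  if (nchar(object@tagSequence) != object@tagLength)
    msg <- c(msg, "tagSequence length must equal tagLength")
  if (grepl("[^ACGT]", object@tagSequence))
    msg <- c(msg, "tagSequence must contain only A, C, G, T")
  if (object@depthPerSample <= 0L)
    msg <- c(msg, "depthPerSample must be > 0")
  if (length(object@generations) < 1L || any(object@generations < 0))
    msg <- c(msg, "generations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param nGenes,geneLength,intergenicLength,essentialFraction,insertionDensity,readLength,tagLength,tagSequence,depthPerSample,generations,seed
#'   see the corresponding slots.
#' @return `simConfig()` returns a validated `SimConfig` object.
#' @rdname SimConfig-class
#' @examples
#' cfg <- simConfig(nGenes = 10, depthPerSample = 1000, seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes = 200L, geneLength = 600L,
                      intergenicLength = 150L, essentialFraction = 0.05,
                      insertionDensity = 47, readLength = 50L,
                      tagLength = 10L, tagSequence = "CTGTCTCTTA",
                      depthPerSample = 200000L,
                      generations = c(3, 5, 4.5, 7.5), seed = 1L) {
  new("SimConfig",
    nGenes = as.integer(nGenes), geneLength = as.integer(geneLength),
    intergenicLength = as.integer(intergenicLength),
    essentialFraction = as.numeric(essentialFraction),
    insertionDensity = as.numeric(insertionDensity),
    readLength = as.integer(readLength), tagLength = as.integer(tagLength),
    tagSequence = as.character(tagSequence),
    depthPerSample = as.integer(depthPerSample),
    generations = as.numeric(generations), seed = as.integer(seed)
  )
}

setMethod("show", "SimConfig", function(object) {
  len <- (object@nGenes + 1L) * object@intergenicLength +
    object@nGenes * object@geneLength
  cat("SimConfig:", object@nGenes, "genes,", len, "bp genome\n")
  cat("  insertion density 1 /", object@insertionDensity, "bp;",
      "reads", object@readLength, "bp with", object@tagLength, "bp tag\n")
  cat("  depth", object@depthPerSample, "reads/sample;",
      length(object@generations), "replicate selections (generations",
      paste(object@generations, collapse = ", "), ")\n")
})

#' Annotated reference genome for a transposon screen
#'
#' A `TnGenome` couples a chromosome sequence with its gene annotation:
#' non-overlapping gene intervals, each with a stable identifier and an
#' essentiality flag. It is the coordinate frame for insertion mapping and
#' gene-level counting. Coordinates are 1-based inclusive ([GRanges]
#' convention); the chromosome is treated as circular by the read simulator
#' and the mapper.
#'
#' @slot sequence a [Biostrings::DNAString] with the chromosome sequence.
#' @slot genes a [GenomicRanges::GRanges] with metadata columns `gene_id`
#'   (unique character) and `essential` (logical).
#'
#' @seealso [tnGenome()], [simulateGenome()], [readTnGenome()]
#' @export
setClass("TnGenome",
  representation(sequence = "DNAString", genes = "GRanges")
)

setValidity("TnGenome", function(object) {
  msg <- character()
  g <- object@genes
  L <- length(object@sequence)
  if (!all(c("gene_id", "essential") %in% names(S4Vectors::mcols(g))))
    msg <- c(msg, "genes must carry gene_id and essential metadata columns")
  else {
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "gene_id values must be unique")
    if (!is.logical(g$essential)) msg <- c(msg, "essential must be logical")
  }
  if (length(g)) {
    if (min(GenomicRanges::start(g)) < 1L || max(GenomicRanges::end(g)) > L)
      msg <- c(msg, "gene intervals must lie within the genome")
    ov <- GenomicRanges::findOverlaps(g, ignore.strand = TRUE,
                                      drop.self = TRUE)
    if (length(ov)) msg <- c(msg, "gene intervals must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' @param sequence chromosome sequence (`DNAString` or character scalar).
#' @param genes `GRanges` of gene intervals with `gene_id` and `essential`
#'   metadata columns.
#' @return `tnGenome()` returns a validated `TnGenome`.
#' @rdname TnGenome-class
#' @export
tnGenome <- function(sequence, genes) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("TnGenome", sequence = sequence, genes = genes)
}

#' @rdname TnGenome-class
#' @param x a `TnGenome`.
#' @export
setMethod("genomeLength", "TnGenome", function(x) length(x@sequence))

#' @rdname TnGenome-class
#' @export
setMethod("genomeSequence", "TnGenome", function(x) x@sequence)

#' @rdname TnGenome-class
#' @export
setMethod("geneRanges", "TnGenome", function(x) x@genes)

setMethod("show", "TnGenome", function(object) {
  g <- object@genes
  cat("TnGenome:", length(object@sequence), "bp,", length(g), "genes (",
      sum(g$essential), "essential )\n")
})

#' Per-gene relative fitness under phage selection
#'
#' A `FitnessMap` assigns each gene a relative fitness `w` of its
#' insertion mutants under phage selection: `w = 1` is neutral, `w > 1`
#' models mutants of susceptibility genes expanding because they are not
#' killed as readily, and `w < 1` models mutants of resistance genes being
#' depleted. Insertions outside any gene take `defaultW`; genes absent from
#' `w` are neutral.
#'
#' @slot w named numeric vector of per-gene fitness values (names are
#'   `gene_id`s).
#' @slot defaultW fitness applied to intergenic insertions.
#'
#' @seealso [applySelection()], [screenFitness()]
#' @export
setClass("FitnessMap",
  representation(w = "numeric", defaultW = "numeric")
)

setValidity("FitnessMap", function(object) {
  msg <- character()
  if (length(object@w) && is.null(names(object@w)))
    msg <- c(msg, "w must be named by gene_id")
  if (any(object@w < 0) || object@defaultW < 0)
    msg <- c(msg, "fitness values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param w named numeric vector of per-gene fitness values.
#' @param defaultW fitness for intergenic insertions (default 1, neutral).
#' @return `fitnessMap()` returns a validated `FitnessMap`.
#' @rdname FitnessMap-class
#' @examples
#' fitnessMap(c(gene_0001 = 2, gene_0002 = 0.5))
#' @export
fitnessMap <- function(w = numeric(0), defaultW = 1) {
  new("FitnessMap", w = setNames(as.numeric(w), names(w)),
      defaultW = as.numeric(defaultW))
}

setMethod("show", "FitnessMap", function(object) {
  cat("FitnessMap:", length(object@w), "genes with explicit w;",
      "defaultW =", object@defaultW, "\n")
  if (length(object@w)) {
    eff <- object@w[object@w != 1]
    cat("  non-neutral genes:", length(eff), "\n")
  }
})

#' Pooled transposon mutant library
#'
#' A `MutantLibrary` is the set of insertion mutants in a pooled library:
#' one record per unique (position, strand) transposon junction, with a
#' relative abundance. Same-position insertions in opposite orientations
#' are distinct mutants. Essential genes carry no insertions because such
#' mutants are never recovered.
#'
#' @slot insertions width-1 [GenomicRanges::GRanges] of junctions with an
#'   `abundance` metadata column (non-negative numeric).
#' @slot genomeLength genome length in bp.
#'
#' @seealso [simulateLibrary()], [applySelection()], [generateReads()]
#' @export
setClass("MutantLibrary",
  representation(insertions = "GRanges", genomeLength = "integer")
)

setValidity("MutantLibrary", function(object) {
  msg <- character()
  ins <- object@insertions
  if (!"abundance" %in% names(S4Vectors::mcols(ins)))
    msg <- c(msg, "insertions must carry an abundance metadata column")
  else if (any(ins$abundance < 0))
    msg <- c(msg, "abundances must be non-negative")
  if (length(ins)) {
    if (any(GenomicRanges::width(ins) != 1L))
      msg <- c(msg, "insertions must be width-1 junction positions")
    if (min(GenomicRanges::start(ins)) < 1L ||
        max(GenomicRanges::start(ins)) > object@genomeLength)
      msg <- c(msg, "insertion positions must lie within the genome")
    if (any(as.character(GenomicRanges::strand(ins)) == "*"))
      msg <- c(msg, "insertion strands must be + or -")
    key <- paste(GenomicRanges::start(ins),
                 as.character(GenomicRanges::strand(ins)))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (position, strand) insertions")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MutantLibrary-class
#' @param x a `MutantLibrary`.
#' @export
setMethod("insertions", "MutantLibrary", function(x) x@insertions)

#' @rdname MutantLibrary-class
#' @export
setMethod("genomeLength", "MutantLibrary", function(x) x@genomeLength)

#' @rdname MutantLibrary-class
#' @export
setMethod("uis", "MutantLibrary", function(x) length(x@insertions))

setMethod("show", "MutantLibrary", function(object) {
  n <- length(object@insertions)
  cat("MutantLibrary:", n, "unique insertion sites on a",
      object@genomeLength, "bp genome\n")
  if (n > 0)
    cat("  density: 1 insertion /",
        round(object@genomeLength / n, 1), "bp\n")
})

#' Transposon tag specification
#'
#' Describes the transposon-derived prefix expected at the start of every
#' read and the number of mismatches tolerated when verifying it.
#'
#' @slot tagSequence the expected prefix (A/C/G/T).
#' @slot maxMismatches Hamming mismatches tolerated (default 0, strict).
#'
#' @seealso [checkAndTrimTag()], [processReads()]
#' @export
setClass("TagSpec",
  representation(tagSequence = "character", maxMismatches = "integer")
)

setValidity("TagSpec", function(object) {
  msg <- character()
  if (nchar(object@tagSequence) < 1L)
    msg <- c(msg, "tag must have length >= 1")
  if (grepl("[^ACGT]", object@tagSequence))
    msg <- c(msg, "tag must contain only A, C, G, T")
  if (object@maxMismatches < 0L)
    msg <- c(msg, "maxMismatches must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param tagSequence expected read prefix.
#' @param maxMismatches tolerated Hamming mismatches.
#' @return `tagSpec()` returns a validated `TagSpec`.
#' @rdname TagSpec-class
#' @examples
#' tagSpec("CTGTCTCTTA")
#' @export
tagSpec <- function(tagSequence = "CTGTCTCTTA", maxMismatches = 0L) {
  new("TagSpec", tagSequence = as.character(tagSequence),
      maxMismatches = as.integer(maxMismatches))
}

setMethod("show", "TagSpec", function(object) {
  cat("TagSpec:", object@tagSequence, "(",
      object@maxMismatches, "mismatches tolerated )\n")
})

#' Per-sample insertion profile
#'
#' An `InsertionProfile` records, for one sequenced sample, the read count
#' observed at every unique (position, strand) transposon junction, plus
#' the bookkeeping totals of the read-processing pipeline. Reads are fully
#' partitioned into tag-rejected, unmapped, ambiguous and mapped classes,
#' and the site counts sum exactly to the mapped reads.
#'
#' @slot sites width-1 [GenomicRanges::GRanges] of junctions with a
#'   `count` metadata column.
#' @slot genomeLength genome length in bp.
#' @slot nReadsTotal,nReadsTagged,nReadsMapped,nReadsAmbiguous,nReadsUnmapped
#'   bookkeeping totals; tag-rejected reads are
#'   `nReadsTotal - nReadsTagged`, and
#'   `nReadsTagged = nReadsMapped + nReadsAmbiguous + nReadsUnmapped`.
#'
#' @seealso [buildInsertionProfile()], [processReads()],
#'   [writeInsertionProfile()]
#' @export
setClass("InsertionProfile",
  representation(
    sites = "GRanges", genomeLength = "integer",
    nReadsTotal = "integer", nReadsTagged = "integer",
    nReadsMapped = "integer", nReadsAmbiguous = "integer",
    nReadsUnmapped = "integer"
  )
)

setValidity("InsertionProfile", function(object) {
  msg <- character()
  s <- object@sites
  if (!"count" %in% names(S4Vectors::mcols(s)))
    msg <- c(msg, "sites must carry a count metadata column")
  else {
    if (any(s$count < 1L)) msg <- c(msg, "site counts must be >= 1")
    if (sum(s$count) != object@nReadsMapped)
      msg <- c(msg, "site counts must sum to nReadsMapped")
  }
  if (length(s)) {
    if (min(GenomicRanges::start(s)) < 1L ||
        max(GenomicRanges::start(s)) > object@genomeLength)
      msg <- c(msg, "site positions must lie within the genome")
    key <- paste(GenomicRanges::start(s),
                 as.character(GenomicRanges::strand(s)))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (position, strand) sites")
  }
  if (object@nReadsTagged >
      object@nReadsTotal ||
      object@nReadsMapped + object@nReadsAmbiguous + object@nReadsUnmapped !=
      object@nReadsTagged)
    msg <- c(msg, "read bookkeeping totals are inconsistent")
  if (length(msg)) msg else TRUE
})

#' @rdname InsertionProfile-class
#' @param x an `InsertionProfile`.
#' @export
setMethod("insertionSites", "InsertionProfile", function(x) x@sites)

#' @rdname InsertionProfile-class
#' @export
setMethod("genomeLength", "InsertionProfile", function(x) x@genomeLength)

#' @rdname InsertionProfile-class
#' @export
setMethod("uis", "InsertionProfile", function(x) length(x@sites))

#' @describeIn InsertionProfile-class named integer vector with elements
#'   `total`, `tagged`, `rejected`, `mapped`, `ambiguous`, `unmapped`.
#' @export
setMethod("readStats", "InsertionProfile", function(x) {
  c(total = x@nReadsTotal, tagged = x@nReadsTagged,
    rejected = x@nReadsTotal - x@nReadsTagged,
    mapped = x@nReadsMapped, ambiguous = x@nReadsAmbiguous,
    unmapped = x@nReadsUnmapped)
})

setMethod("show", "InsertionProfile", function(object) {
  cat("InsertionProfile:", length(object@sites),
      "unique insertion sites,", object@nReadsMapped, "mapped /",
      object@nReadsTotal, "total reads\n")
})

#' Gene-level count table for a transposon screen
#'
#' `TnGeneCounts` extends [SummarizedExperiment::SummarizedExperiment] with
#' two assays over genes x samples: `reads` (reads whose junction falls
#' inside the gene) and `sites` (unique insertion sites inside the gene).
#' `rowData` carries `gene_id`, `gene_length` and, after
#' [flagUnassayable()], the `assayable` flag; `colData` carries the mapped
#' read total and the intergenic bucket (reads and sites whose junction
#' falls outside every gene) of each sample, so counts remain conserved.
#'
#' @seealso [geneCountTable()], [flagUnassayable()], [compareSamples()]
#' @export
setClass("TnGeneCounts", contains = "SummarizedExperiment")

setValidity("TnGeneCounts", function(object) {
  msg <- character()
  if (!all(c("reads", "sites") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'reads' and 'sites' are required")
  else if (any(SummarizedExperiment::assay(object, "reads") <
               SummarizedExperiment::assay(object, "sites")))
    msg <- c(msg, "read counts cannot be smaller than insertion-site counts")
  if (!all(c("gene_id", "gene_length") %in%
           names(SummarizedExperiment::rowData(object))))
    msg <- c(msg, "rowData must carry gene_id and gene_length")
  if (length(msg)) msg else TRUE
})

#' @describeIn TnGeneCounts-class logical vector of assayable flags
#'   (`NA` before [flagUnassayable()] has been applied).
#' @param x a `TnGeneCounts`.
#' @export
setMethod("assayable", "TnGeneCounts", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("assayable" %in% names(rd)) rd$assayable
  else rep(NA, nrow(x))
})

#' Cutoffs for calling susceptibility and resistance genes
#'
#' The screen calls a gene in one comparison when its log2 fold change is
#' at least `logfcCut` in magnitude (inclusive), its q value is below
#' `qCut` and its p value is below `pCut`. Defaults are the screen's
#' published criteria: |logFC| >= 2, q < 0.01, p < 0.05.
#'
#' @slot logfcCut positive log2 fold-change threshold (inclusive).
#' @slot qCut FDR (q value) threshold (exclusive).
#' @slot pCut p value threshold (exclusive).
#'
#' @seealso [classifyGenes()], [consensusCalls()]
#' @export
setClass("CutoffConfig",
  representation(logfcCut = "numeric", qCut = "numeric", pCut = "numeric")
)

setValidity("CutoffConfig", function(object) {
  msg <- character()
  if (object@logfcCut <= 0) msg <- c(msg, "logfcCut must be > 0")
  if (object@qCut <= 0 || object@qCut > 1)
    msg <- c(msg, "qCut must be in (0, 1]")
  if (object@pCut <= 0 || object@pCut > 1)
    msg <- c(msg, "pCut must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param logfcCut,qCut,pCut see slots.
#' @return `cutoffConfig()` returns a validated `CutoffConfig`.
#' @rdname CutoffConfig-class
#' @examples
#' cutoffConfig()
#' @export
cutoffConfig <- function(logfcCut = 2, qCut = 0.01, pCut = 0.05) {
  new("CutoffConfig", logfcCut = as.numeric(logfcCut),
      qCut = as.numeric(qCut), pCut = as.numeric(pCut))
}

setMethod("show", "CutoffConfig", function(object) {
  cat("CutoffConfig: |logFC| >=", object@logfcCut, ", q <", object@qCut,
      ", p <", object@pCut, "\n")
})

#' Per-comparison test configuration
#'
#' @slot pseudocount positive value added to counts-per-million before the
#'   fold-change ratio, keeping log fold changes finite (default 0.5).
#'
#' @seealso [compareSamples()], [logFoldChange()]
#' @export
setClass("TestConfig", representation(pseudocount = "numeric"))

setValidity("TestConfig", function(object) {
  if (object@pseudocount <= 0) "pseudocount must be > 0" else TRUE
})

#' @param pseudocount pseudocount on the CPM scale.
#' @return `testConfig()` returns a validated `TestConfig`.
#' @rdname TestConfig-class
#' @export
testConfig <- function(pseudocount = 0.5) {
  new("TestConfig", pseudocount = as.numeric(pseudocount))
}

#' Ordinal lysis profile of one strain across a phage panel
#'
#' A `LysisProfile` stores plaque-assay outcomes for one strain against a
#' panel of typing phages, on the ordinal scale 0 = full resistance ("-"),
#' 1 = partial lysis ("(+)"), 2 = full lysis ("+"). Optionally a dilution
#' depth per phage records the highest dilution step still cleared (0 =
#' undiluted only; -1 = none cleared).
#'
#' @slot strainId strain identifier.
#' @slot grades named integer vector (phage id -> grade in 0:2).
#' @slot depths optional named integer vector of dilution depths (same
#'   names as `grades`, or empty).
#'
#' @seealso [lysisProfile()], [gradeLysis()], [compareProfiles()]
#' @export
setClass("LysisProfile",
  representation(strainId = "character", grades = "integer",
                 depths = "integer")
)

setValidity("LysisProfile", function(object) {
  msg <- character()
  if (is.null(names(object@grades)) || anyDuplicated(names(object@grades)))
    msg <- c(msg, "grades must be uniquely named by phage id")
  if (any(!object@grades %in% 0:2))
    msg <- c(msg, "grades must be on the ordinal scale 0, 1, 2")
  if (length(object@depths) &&
      !identical(sort(names(object@depths)), sort(names(object@grades))))
    msg <- c(msg, "depths must cover the same phage panel as grades")
  if (length(msg)) msg else TRUE
})

#' @param strainId strain identifier.
#' @param grades named integer vector of grades (0/1/2) per phage.
#' @param depths optional named integer vector of dilution depths.
#' @return `lysisProfile()` returns a validated `LysisProfile`.
#' @rdname LysisProfile-class
#' @examples
#' lysisProfile("WT", c(TP1 = 2, TP8 = 1, TP16 = 0))
#' @export
lysisProfile <- function(strainId, grades, depths = integer(0)) {
  new("LysisProfile", strainId = as.character(strainId),
      grades = setNames(as.integer(grades), names(grades)),
      depths = setNames(as.integer(depths), names(depths)))
}

setMethod("show", "LysisProfile", function(object) {
  tok <- c("-", "(+)", "+")[object@grades + 1L]
  cat("LysisProfile", object@strainId, ":",
      paste(names(object@grades), tok, sep = "=", collapse = " "), "\n")
})
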