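#' @import methods
#' @importFrom stats dbinom p.adjust rbinom rmultinom runif setNames
#' @importFrom utils read.delim write.table
NULL

#' Genome length of an object
#'
#' Length in base pairs of the (circular) reference chromosome an object is
#' defined on.
#'
#' @param x a [TnGenome], [MutantLibrary], [InsertionProfile] or
#'   [GenomeIndex] object.
#' @return Integer scalar, genome length in bp.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname TnGenome-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname TnGenome-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname MutantLibrary-class
#' @export
setGeneric("insertions", function(x) standardGeneric("insertions"))

#' @rdname InsertionProfile-class
#' @export
setGeneric("insertionSites", function(x) standardGeneric("insertionSites"))

#' Number of unique insertion sites
#'
#' Unique insertion sites (UIS) are distinct (position, strand) transposon
#' junctions; the same coordinate hit on both strands counts as two sites,
#' since the two orientations are distinct mutants.
#'
#' @param x a [MutantLibrary] or [InsertionProfile].
#' @return Integer scalar.
#' @export
setGeneric("uis", function(x) standardGeneric("uis"))

#' @rdname InsertionProfile-class
#' @export
setGeneric("readStats", function(x) standardGeneric("readStats"))

#' @rdname TnGeneCounts-class
#' @export
setGeneric("assayable", function(x) standardGeneric("assayable"))
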