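#' Verify and strip the transposon tag from reads
#'
#' A genuine transposon-junction read begins with the transposon tag;
#' reads whose prefix differs from the tag by more than
#' `spec@maxMismatches` Hamming mismatches are rejected, as are reads no
#' longer than the tag itself (distinct reason code). Accepted reads are
#' returned with the tag removed.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of raw
#'   reads.
#' @param spec a [TagSpec].
#' @return A list with `trimmed` (character; `NA` for rejected reads) and
#'   `status` (factor with levels `tagged`, `tag_mismatch`, `too_short`).
#' @examples
#' checkAndTrimTag(c("CTGTCTCTTAACGTACGT", "AAAAAAAAAAACGTACGT", "CTG"),
#'                 tagSpec("CTGTCTCTTA"))
#' @export
checkAndTrimTag <- function(reads, spec = tagSpec()) {
  validObject(spec)
  if (!is.character(reads)) reads <- as.character(reads)
  tl <- nchar(spec@tagSequence)
  len <- nchar(reads)
  tooShort <- len <= tl
  prefix <- substr(reads, 1L, tl)
  if (spec@maxMismatches == 0L) {
    ok <- prefix == spec@tagSequence
  } else {
    mm <- integer(length(reads))
    for (j in seq_len(tl))
      mm <- mm + (substr(prefix, j, j) != substr(spec@tagSequence, j, j))
    ok <- mm <= spec@maxMismatches
  }
  status <- rep("tagged", length(reads))
  status[!ok] <- "tag_mismatch"
  status[tooShort] <- "too_short"
  trimmed <- rep(NA_character_, length(reads))
  keep <- status == "tagged"
  trimmed[keep] <- substr(reads[keep], tl + 1L, len[keep])
  list(trimmed = trimmed,
       status = factor(status, levels = c("tagged", "tag_mismatch",
                                          "too_short")))
}

#' Exact-match k-mer index of a circular genome
#'
#' Indexes every k-mer starting position of the (circular) forward strand.
#' Queries are looked up on both strands: a trimmed read maps uniquely if
#' its sequence occurs exactly once in the genome across both
#' orientations. Synthetic junction reads are error-free, so exact
#' placement replaces a full aligner; externally mapped real data can be
#' ingested instead via [readInsertionProfile()].
#'
#' @slot k k-mer (trimmed read) length.
#' @slot genomeLength genome length in bp.
#' @slot table unique k-mers present in the forward strand.
#' @slot occ occurrence count of each unique k-mer.
#' @slot firstPos first (1-based) start position of each unique k-mer.
#' @seealso [genomeIndex()], [mapReads()]
#' @export
setClass("GenomeIndex",
  representation(k = "integer", genomeLength = "integer",
                 table = "character", occ = "integer", firstPos = "integer")
)

#' @rdname GenomeIndex-class
#' @param x a `GenomeIndex`.
#' @export
setMethod("genomeLength", "GenomeIndex", function(x) x@genomeLength)

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex: k =", object@k, "on a", object@genomeLength,
      "bp circular genome;", length(object@table), "distinct k-mers\n")
})

#' @param genome a [TnGenome].
#' @param k k-mer length; defaults in [processReads()] to the trimmed read
#'   length.
#' @return `genomeIndex()` returns a `GenomeIndex`.
#' @rdname GenomeIndex-class
#' @export
genomeIndex <- function(genome, k) {
  L <- genomeLength(genome)
  k <- as.integer(k)
  if (k < 1L || k > L) stop("k must be in [1, genome length]")
  gseq <- as.character(genomeSequence(genome))
  ext <- paste0(gseq, substr(gseq, 1L, k - 1L))
  kmers <- substring(ext, seq_len(L), seq_len(L) + k - 1L)
  u <- unique(kmers)
  idx <- match(kmers, u)
  new("GenomeIndex", k = k, genomeLength = L, table = u,
      occ = tabulate(idx, length(u)),
      firstPos = match(u, kmers))
}

#' Map trimmed reads to the genome by exact placement
#'
#' Each trimmed read is placed by exact match against the circular genome
#' on both strands. The reported coordinate is the first genomic base
#' after the transposon junction in the forward reference frame: the match
#' start for a forward-strand placement, the match end for a
#' reverse-strand placement. Reads matching more than one location
#' (counting both strands) are `ambiguous` and discarded rather than
#' assigned at random, which would create phantom insertion sites; reads
#' matching nowhere are `unmapped`.
#'
#' @param trimmed character vector of tag-stripped reads, each exactly
#'   `index@k` long (`NA` entries, e.g. tag-rejected reads, are ignored
#'   and returned as `NA` rows).
#' @param index a [GenomeIndex].
#' @return A data.frame with columns `position` (1-based), `strand` and
#'   `status` (factor `mapped`/`ambiguous`/`unmapped`), one row per input.
#' @examples
#' g <- simulateGenome(simConfig(nGenes = 2, seed = 1))
#' idx <- genomeIndex(g, k = 40)
#' r <- substr(as.character(genomeSequence(g)), 11, 50)
#' mapReads(r, idx)
#' @export
mapReads <- function(trimmed, index) {
  stopifnot(is(index, "GenomeIndex"))
  if (!is.character(trimmed)) trimmed <- as.character(trimmed)
  live <- !is.na(trimmed)
  if (any(nchar(trimmed[live]) != index@k))
    stop("trimmed reads must all have length k = ", index@k)
  if (any(nchar(trimmed[live]) == 0L)) stop("empty trimmed read")
  u <- unique(trimmed[live])
  rc <- as.character(reverseComplement(DNAStringSet(u)))
  iF <- match(u, index@table)
  iR <- match(rc, index@table)
  occF <- ifelse(is.na(iF), 0L, index@occ[iF])
  occR <- ifelse(is.na(iR), 0L, index@occ[iR])
  hits <- occF + occR
  status <- ifelse(hits == 0L, "unmapped",
                   ifelse(hits > 1L, "ambiguous", "mapped"))
  pos <- rep(NA_integer_, length(u))
  str <- rep(NA_character_, length(u))
  isF <- status == "mapped" & occF == 1L
  isR <- status == "mapped" & occR == 1L
  pos[isF] <- index@firstPos[iF[isF]]
  str[isF] <- "+"
  pos[isR] <- (index@firstPos[iR[isR]] + index@k - 2L) %% index@genomeLength + 1L
  str[isR] <- "-"
  m <- match(trimmed, u)
  data.frame(position = pos[m], strand = str[m],
             status = factor(status[m],
                             levels = c("mapped", "ambiguous", "unmapped")))
}

#' Aggregate read mappings into an insertion profile
#'
#' Collapses mapped reads onto unique (position, strand) junctions,
#' recording the read count at each; the same coordinate on opposite
#' strands yields two distinct sites. Bookkeeping totals keep the read
#' partition exact: `total = rejected + unmapped + ambiguous + mapped`.
#'
#' @param mappings data.frame as returned by [mapReads()] (only rows with
#'   `status == "mapped"` contribute sites).
#' @param genomeLength genome length in bp.
#' @param nReadsTotal,nReadsTagged totals from upstream tag processing;
#'   default to treating all mapper input as tagged.
#' @return An [InsertionProfile].
#' @export
buildInsertionProfile <- function(mappings, genomeLength,
                                  nReadsTotal = nrow(mappings),
                                  nReadsTagged = nrow(mappings)) {
  ok <- !is.na(mappings$status) & mappings$status == "mapped"
  nAmb <- sum(mappings$status == "ambiguous", na.rm = TRUE)
  nUnm <- sum(mappings$status == "unmapped", na.rm = TRUE)
  if (sum(ok) > 0L) {
    key <- paste0(mappings$position[ok], mappings$strand[ok])
    agg <- rowsum(rep(1L, sum(ok)), key, reorder = FALSE)
    first <- !duplicated(key)
    sites <- GRanges("chr",
                     IRanges(mappings$position[ok][first], width = 1L),
                     strand = mappings$strand[ok][first],
                     count = as.integer(agg[match(unique(key),
                                                  rownames(agg))]))
    sites <- GenomicRanges::sort(sites, ignore.strand = TRUE)
  } else {
    sites <- GRanges(count = integer(0))
  }
  new("InsertionProfile", sites = sites,
      genomeLength = as.integer(genomeLength),
      nReadsTotal = as.integer(nReadsTotal),
      nReadsTagged = as.integer(nReadsTagged),
      nReadsMapped = as.integer(sum(ok)),
      nReadsAmbiguous = as.integer(nAmb),
      nReadsUnmapped = as.integer(nUnm))
}

#' Process raw tagged reads into an insertion profile
#'
#' The per-sample pipeline: verify and strip the transposon tag
#' ([checkAndTrimTag()]), place the genomic remainder by exact match on
#' the circular genome ([mapReads()]), and aggregate unique junctions
#' ([buildInsertionProfile()]). Reads are fully partitioned into
#' tag-rejected, unmapped, ambiguous and mapped classes.
#'
#' @param reads raw reads (character or [Biostrings::DNAStringSet]).
#' @param genome a [TnGenome] (ignored when `index` is supplied).
#' @param spec a [TagSpec].
#' @param index optional pre-built [GenomeIndex]; build it once with
#'   [genomeIndex()] when processing several samples of one screen.
#' @return An [InsertionProfile].
#' @examples
#' cfg <- simConfig(nGenes = 2, depthPerSample = 500, seed = 2)
#' sim <- simulateScreen(cfg, fitness = fitnessMap())
#' p <- processReads(sim$reads$control, sim$genome,
#'                   tagSpec(cfg@tagSequence))
#' readStats(p)
#' @export
processReads <- function(reads, genome, spec = tagSpec(), index = NULL) {
  if (!is.character(reads)) reads <- as.character(reads)
  tt <- checkAndTrimTag(reads, spec)
  keep <- tt$status == "tagged"
  if (is.null(index)) {
    klen <- nchar(tt$trimmed[keep])
    if (!length(klen)) stop("no tagged reads to map")
    if (length(unique(klen)) != 1L)
      stop("tagged reads have unequal trimmed lengths")
    index <- genomeIndex(genome, k = klen[1L])
  }
  mp <- mapReads(tt$trimmed[keep], index)
  buildInsertionProfile(mp, genomeLength(index),
                        nReadsTotal = length(reads),
                        nReadsTagged = sum(keep))
}
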