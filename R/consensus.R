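#' Classify genes in one comparison
#'
#' Applies the screen's cutoffs to one selected-vs-control comparison:
#' a gene is a susceptibility gene when `logFC >= logfcCut` (insertion
#' mutants expanded, so the intact gene normally aids phage killing), a
#' resistance gene when `logFC <= -logfcCut` (mutants depleted, so the
#' gene normally protects), in both cases requiring `q < qCut` and
#' `p < pCut`; anything else is `none`. The fold-change threshold is
#' inclusive (>= 2 / <= -2 at the defaults), the significance thresholds
#' strict.
#'
#' @param logFC,p,q numeric vectors of equal length (finite).
#' @param cuts a [CutoffConfig].
#' @return Factor with levels `susceptibility`, `resistance`, `none`.
#' @examples
#' classifyGenes(c(8.48, -9.54, -0.04), p = c(1e-6, 1e-6, 1e-6),
#'               q = c(1e-4, 1e-4, 1e-4))
#' @export
classifyGenes <- function(logFC, p, q, cuts = cutoffConfig()) {
  validObject(cuts)
  if (any(!is.finite(logFC)) || any(!is.finite(p)) || any(!is.finite(q)))
    stop("logFC, p and q must be finite")
  sig <- q < cuts@qCut & p < cuts@pCut
  cls <- rep("none", length(logFC))
  cls[sig & logFC >= cuts@logfcCut] <- "susceptibility"
  cls[sig & logFC <= -cuts@logfcCut] <- "resistance"
  factor(cls, levels = c("susceptibility", "resistance", "none"))
}

#' Consensus susceptibility/resistance calls across replicate selections
#'
#' Intersects the replicate comparisons (by design four: two phage doses
#' at two exposure times, each against the untreated control): a gene is
#' called only when [classifyGenes()] returns the same non-`none` class in
#' every replicate, and its reported effect is the arithmetic mean of its
#' log2 fold changes over all replicates. `n_passing` records the largest
#' number of replicates agreeing on one class, so near-misses (e.g. 3 of
#' 4) are visible but not called.
#'
#' @param results list of comparison tables from [compareSamples()] (or
#'   any tables with `gene_id`, `logFC`, `p`, `q`), all over the same
#'   gene set.
#' @param cuts a [CutoffConfig].
#' @return A [S4Vectors::DataFrame] with `gene_id`, `class`
#'   (`susceptibility`/`resistance`/`none`), `mean_logFC` and
#'   `n_passing`.
#' @export
consensusCalls <- function(results, cuts = cutoffConfig()) {
  if (!length(results)) stop("no comparison results supplied")
  ids <- results[[1L]]$gene_id
  aligned <- lapply(results, function(r) {
    if (!setequal(r$gene_id, ids))
      stop("comparisons cover different gene sets")
    r[match(ids, r$gene_id), ]
  })
  cls <- vapply(aligned,
                function(r) as.character(classifyGenes(r$logFC, r$p, r$q,
                                                       cuts)),
                character(length(ids)))
  dim(cls) <- c(length(ids), length(aligned))
  lfc <- vapply(aligned, function(r) r$logFC, numeric(length(ids)))
  dim(lfc) <- dim(cls)
  m <- length(aligned)
  nSus <- rowSums(cls == "susceptibility")
  nRes <- rowSums(cls == "resistance")
  call <- rep("none", length(ids))
  call[nSus == m] <- "susceptibility"
  call[nRes == m] <- "resistance"
  DataFrame(gene_id = ids,
            class = factor(call,
                           levels = c("susceptibility", "resistance",
                                      "none")),
            mean_logFC = rowMeans(lfc),
            n_passing = as.integer(pmax(nSus, nRes)))
}
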