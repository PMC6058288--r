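#' Counts per million
#'
#' Library-size normalisation: `cpm = count * 1e6 / librarySize`.
#'
#' @param counts numeric vector of per-gene read counts.
#' @param librarySize total mapped reads of the sample (> 0).
#' @return Numeric vector of counts per million.
#' @examples
#' cpm(c(5, 5), 10)
#' @export
cpm <- function(counts, librarySize) {
  if (librarySize <= 0) stop("librarySize must be > 0")
  counts * 1e6 / librarySize
}

#' Log2 fold change of normalised counts
#'
#' `log2((cpm_sel + pseudocount) / (cpm_ctrl + pseudocount))`: the change
#' in a gene's insertion-read share between a selected sample and the
#' untreated control, on the log counts-per-million scale. The symmetric
#' pseudocount keeps the value finite when either count is zero and
#' makes swapping the two samples negate the result exactly.
#'
#' @param countSel,countCtrl per-gene read counts in the selected and
#'   control samples (vectorised).
#' @param libSel,libCtrl total mapped reads of the two samples.
#' @param pseudocount positive pseudocount on the CPM scale.
#' @return Numeric vector of log2 fold changes.
#' @examples
#' logFoldChange(200, 100, 1e6, 1e6)
#' @export
logFoldChange <- function(countSel, countCtrl, libSel, libCtrl,
                          pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((cpm(countSel, libSel) + pseudocount) /
       (cpm(countCtrl, libCtrl) + pseudocount))
}

#' Exact conditional binomial test of a per-gene count change
#'
#' Conditional on the gene's total count `n = countSel + countCtrl`, under
#' the null hypothesis of no selection effect the selected-sample count is
#' `Binomial(n, pi)` with `pi = libSel / (libSel + libCtrl)`. The
#' two-sided p-value is the minimum-likelihood sum: the total probability
#' of all outcomes whose point probability does not exceed that of the
#' observed count (ties included with relative tolerance 1e-12). When
#' `n = 0` the test is vacuous and p = 1.
#'
#' @param countSel,countCtrl non-negative per-gene counts (vectorised).
#' @param libSel,libCtrl total mapped reads of the two samples.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' binomialCountTest(10, 0, 1e6, 1e6)  # 2 * 0.5^10
#' @export
binomialCountTest <- function(countSel, countCtrl, libSel, libCtrl) {
  if (any(countSel < 0) || any(countCtrl < 0))
    stop("counts must be non-negative")
  if (any(libSel <= 0) || any(libCtrl <= 0))
    stop("library sizes must be > 0")
  m <- max(length(countSel), length(countCtrl))
  countSel <- rep_len(countSel, m)
  countCtrl <- rep_len(countCtrl, m)
  libSel <- rep_len(libSel, m)
  libCtrl <- rep_len(libCtrl, m)
  p <- numeric(m)
  for (i in seq_len(m)) {
    n <- countSel[i] + countCtrl[i]
    if (n == 0) {
      p[i] <- 1
      next
    }
    pi0 <- libSel[i] / (libSel[i] + libCtrl[i])
    d <- dbinom(0:n, n, pi0)
    p[i] <- min(1, sum(d[d <= d[countSel[i] + 1L] * (1 + 1e-12)]))
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and order-preserving.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in the input order.
#' @examples
#' adjustFDR(c(0.01, 0.02, 0.03))
#' @export
adjustFDR <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Compare one selected sample against the untreated control
#'
#' For every assayable gene, computes the log2 fold change of its
#' normalised read count ([logFoldChange()]), an exact conditional
#' binomial p-value ([binomialCountTest()]) and the Benjamini-Hochberg
#' q-value over the assayable gene set ([adjustFDR()]). Library sizes are
#' each sample's total mapped reads. The table must have been passed
#' through [flagUnassayable()] first so that insertion-free (essential)
#' genes are excluded from testing.
#'
#' @param table a [TnGeneCounts] with `assayable` flags.
#' @param selected,control sample names of the contrast.
#' @param config a [TestConfig].
#' @return A [S4Vectors::DataFrame] with columns `gene_id`, `logFC`, `p`,
#'   `q` (one row per assayable gene); the contrast is recorded in
#'   `metadata()`.
#' @export
compareSamples <- function(table, selected, control,
                           config = testConfig()) {
  validObject(config)
  if (!all(c(selected, control) %in% colnames(table)))
    stop("selected and control samples must both be present")
  flag <- assayable(table)
  if (all(is.na(flag)))
    stop("run flagUnassayable() before comparing samples")
  keep <- which(flag)
  if (!length(keep)) stop("no assayable genes to compare")
  reads <- assay(table, "reads")
  libs <- colData(table)$n_reads_mapped
  names(libs) <- colnames(table)
  cs <- reads[keep, selected]
  cc <- reads[keep, control]
  lfc <- logFoldChange(cs, cc, libs[[selected]], libs[[control]],
                       pseudocount = config@pseudocount)
  p <- binomialCountTest(cs, cc, libs[[selected]], libs[[control]])
  res <- DataFrame(gene_id = rowData(table)$gene_id[keep],
                   logFC = unname(lfc), p = unname(p),
                   q = adjustFDR(unname(p)))
  metadata(res) <- list(selected = selected, control = control,
                        pseudocount = config@pseudocount)
  res
}
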