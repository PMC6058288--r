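#' Run the full analysis pipeline on a set of read samples
#'
#' Processes every sample's reads into an insertion profile (tag check,
#' exact junction mapping), builds the gene count table, flags
#' unassayable genes from the untreated control, tests each selected
#' sample against the control and intersects the replicate comparisons
#' into consensus susceptibility/resistance calls.
#'
#' @param reads named list of read vectors (character or
#'   [Biostrings::DNAStringSet]); one element must be the control.
#' @param genome a [TnGenome].
#' @param control name of the untreated control sample.
#' @param spec a [TagSpec] describing the transposon tag.
#' @param minReads control-read threshold for assayability.
#' @param testConf a [TestConfig].
#' @param cuts a [CutoffConfig].
#' @return A list with `profiles`, `counts` (a [TnGeneCounts]),
#'   `comparisons` (one table per selected sample) and `consensus`.
#' @examples
#' cfg <- simConfig(nGenes = 10, depthPerSample = 5000, seed = 11,
#'                  generations = c(3, 5))
#' sim <- simulateScreen(cfg)
#' res <- runScreen(sim$reads, sim$genome, spec = tagSpec(cfg@tagSequence))
#' table(res$consensus$class)
#' @export
runScreen <- function(reads, genome, control = "control",
                      spec = tagSpec(), minReads = 10L,
                      testConf = testConfig(), cuts = cutoffConfig()) {
  if (!control %in% names(reads))
    stop("control sample '", control, "' not among the read samples")
  k <- NULL
  first <- as.character(reads[[1L]][1L])
  k <- nchar(first) - nchar(spec@tagSequence)
  index <- genomeIndex(genome, k = k)
  profiles <- lapply(reads, function(r)
    processReads(r, genome, spec = spec, index = index))
  counts <- geneCountTable(profiles, genome)
  counts <- flagUnassayable(counts, control, minReads = minReads)
  selectedNames <- setdiff(names(reads), control)
  comparisons <- lapply(selectedNames, function(s)
    compareSamples(counts, s, control, config = testConf))
  names(comparisons) <- selectedNames
  list(profiles = profiles, counts = counts, comparisons = comparisons,
       consensus = consensusCalls(comparisons, cuts = cuts))
}

#' Recovery of simulated ground truth by the pipeline
#'
#' Compares consensus calls against the simulator's ground truth.
#' Sensitivity is the fraction of true effect genes (susceptibility or
#' resistance) called with the correct class; precision is the fraction
#' of called genes that are true effect genes of that class. Essential
#' genes are excluded from the truth set since the screen cannot assay
#' them.
#'
#' @param consensus consensus table from [consensusCalls()].
#' @param truth truth data.frame from [simulateScreen()] (columns
#'   `gene_id`, `class`).
#' @return A list with `sensitivity`, `precision`, `n_true`, `n_called`.
#' @export
screenPerformance <- function(consensus, truth) {
  truth <- truth[truth$class != "essential", , drop = FALSE]
  eff <- truth[truth$class %in% c("susceptibility", "resistance"), ]
  called <- consensus[consensus$class != "none", ]
  key <- function(id, cl) paste(id, cl)
  hit <- key(called$gene_id, as.character(called$class)) %in%
    key(eff$gene_id, eff$class)
  sens <- if (nrow(eff)) {
    mean(key(eff$gene_id, eff$class) %in%
           key(called$gene_id, as.character(called$class)))
  } else NA_real_
  prec <- if (nrow(called)) mean(hit) else NA_real_
  list(sensitivity = sens, precision = prec,
       n_true = nrow(eff), n_called = nrow(called))
}
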