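# Small simulation configurations shared across tests.

smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nGenes = 10L, geneLength = 300L, intergenicLength = 100L,
                   essentialFraction = 0.1, depthPerSample = 5000L,
                   generations = c(3, 5), seed = 42L)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# A genome built by hand: two 600-bp genes on a 1500-bp chromosome.
handGenome <- function(seed = 1, essential = c(FALSE, FALSE)) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")
  genes <- GenomicRanges::GRanges("chr",
    IRanges::IRanges(c(101L, 801L), width = 600L), strand = "+",
    gene_id = c("geneA", "geneB"), essential = essential)
  tnGenome(seq, genes)
}

# A mutant library placed at explicit (position, strand) sites.
handLibrary <- function(genome, pos, strand = rep("+", length(pos)),
                        abundance = rep(1, length(pos))) {
  ins <- GenomicRanges::GRanges("chr", IRanges::IRanges(pos, width = 1L),
                                strand = strand, abundance = abundance)
  new("MutantLibrary", insertions = ins,
      genomeLength = genomeLength(genome))
}

# An insertion profile with given sites and one read per count unit.
handProfile <- function(genomeLength, pos, strand, count,
                        extraUnmapped = 0L) {
  ins <- if (length(pos))
    GenomicRanges::GRanges("chr", IRanges::IRanges(pos, width = 1L),
                           strand = strand, count = as.integer(count))
  else GenomicRanges::GRanges(count = integer(0))
  n <- sum(count)
  new("InsertionProfile", sites = ins,
      genomeLength = as.integer(genomeLength),
      nReadsTotal = as.integer(n + extraUnmapped),
      nReadsTagged = as.integer(n + extraUnmapped),
      nReadsMapped = as.integer(n), nReadsAmbiguous = 0L,
      nReadsUnmapped = as.integer(extraUnmapped))
}
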