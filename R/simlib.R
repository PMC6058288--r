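#' Simulate an annotated genome
#'
#' Lays out a circular chromosome as alternating intergenic and gene
#' blocks — an intergenic block before every gene and one after the last,
#' so the genome is `(nGenes + 1) * intergenicLength + nGenes *
#' geneLength` bp — and fills it with uniform random bases. The first
#' `ceiling(nGenes * essentialFraction)` genes are flagged essential; the
#' assignment is deterministic so ground truth is known without
#' bookkeeping.
#'
#' @param config a [SimConfig].
#' @param seed RNG seed (defaults to the config seed). Identical config
#'   and seed give an identical genome.
#' @return A [TnGenome].
#' @examples
#' g <- simulateGenome(simConfig(nGenes = 4, seed = 1))
#' geneRanges(g)
#' @export
simulateGenome <- function(config, seed = config@seed) {
  validObject(config)
  n <- config@nGenes
  gl <- config@geneLength
  il <- config@intergenicLength
  L <- (n + 1L) * il + n * gl
  seq <- withSeed(seed, paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  if (n > 0L) {
    starts <- il + (0:(n - 1L)) * (gl + il) + 1L  # 1-based inclusive
    ess <- seq_len(n) <= ceiling(n * config@essentialFraction)
    genes <- GRanges("chr", IRanges(starts, width = gl), strand = "+",
                     gene_id = sprintf("gene_%04d", seq_len(n)),
                     essential = ess)
  } else {
    genes <- GRanges(gene_id = character(0), essential = logical(0))
  }
  tnGenome(seq, genes)
}

#' Simulate a saturating transposon mutant library
#'
#' Draws candidate insertion sites uniformly over the genome so the
#' expected number of unique insertion sites is `genome length /
#' insertionDensity` (one insertion per 47 bp at the default). Each site
#' gets a uniform random orientation; duplicate (position, strand) draws
#' collapse to one mutant, while the same position in opposite
#' orientations stays two distinct mutants. Sites landing inside an
#' essential gene are rejected — such mutants are never recovered — and
#' every retained insertion starts at abundance 1.
#'
#' @param genome a [TnGenome].
#' @param config a [SimConfig] supplying `insertionDensity`.
#' @param seed RNG seed (defaults to config seed + 1 so the genome and the
#'   library use distinct streams).
#' @return A [MutantLibrary].
#' @examples
#' cfg <- simConfig(nGenes = 4, seed = 1)
#' lib <- simulateLibrary(simulateGenome(cfg), cfg)
#' uis(lib)
#' @export
simulateLibrary <- function(genome, config, seed = config@seed + 1L) {
  validObject(config)
  L <- genomeLength(genome)
  if (L == 0L) stop("cannot build a library on a zero-length genome")
  dat <- withSeed(seed, {
    n <- rbinom(1L, L, min(1, 1 / config@insertionDensity))
    data.frame(pos = sample.int(L, n, replace = TRUE),
               strand = sample(c("+", "-"), n, replace = TRUE))
  })
  dat <- dat[!duplicated(dat), , drop = FALSE]
  ins <- GRanges("chr", IRanges(dat$pos, width = 1L), strand = dat$strand)
  ess <- geneRanges(genome)
  ess <- ess[ess$essential]
  if (length(ess)) {
    hit <- GenomicRanges::countOverlaps(ins, ess, ignore.strand = TRUE)
    ins <- ins[hit == 0L]
  }
  ins <- GenomicRanges::sort(ins, ignore.strand = TRUE)
  ins$abundance <- rep(1, length(ins))
  new("MutantLibrary", insertions = ins, genomeLength = L)
}

#' Apply phage selection to a mutant library
#'
#' Deterministic exponential selection: each insertion's abundance is
#' multiplied by `w^generations`, where `w` is the fitness of the gene
#' containing the insertion (`defaultW` for intergenic insertions; genes
#' absent from the map are neutral), then abundances are renormalised to
#' sum to 1. All stochasticity lives in read generation, so the selection
#' itself is exactly reproducible.
#'
#' @param library a [MutantLibrary].
#' @param genome the [TnGenome] the library was built on.
#' @param fitness a [FitnessMap].
#' @param generations non-negative number of effective selection
#'   generations; dose and exposure time both scale kill-off, so a
#'   stronger dose is simply more generations.
#' @return A [MutantLibrary] with post-selection abundances summing to 1.
#' @examples
#' cfg <- simConfig(nGenes = 4, essentialFraction = 0, seed = 1)
#' g <- simulateGenome(cfg)
#' lib <- simulateLibrary(g, cfg)
#' sel <- applySelection(lib, g, fitnessMap(c(gene_0002 = 2)), generations = 3)
#' @export
applySelection <- function(library, genome, fitness, generations) {
  if (generations < 0) stop("generations must be >= 0")
  validObject(fitness)
  ins <- insertions(library)
  if (!length(ins)) stop("cannot select an empty library")
  w <- rep(fitness@defaultW, length(ins))
  hits <- findOverlaps(ins, geneRanges(genome), ignore.strand = TRUE)
  gid <- geneRanges(genome)$gene_id[S4Vectors::subjectHits(hits)]
  wg <- fitness@w[gid]
  wg[is.na(wg)] <- 1
  w[S4Vectors::queryHits(hits)] <- wg
  ab <- ins$abundance * w^generations
  tot <- sum(ab)
  if (tot <= 0) stop("selection removed every mutant (all-zero abundance)")
  ins$abundance <- ab / tot
  new("MutantLibrary", insertions = ins, genomeLength = library@genomeLength)
}

# Per-site read sequence (tag + genomic suffix) for every insertion of a
# library; the chromosome is circular, so suffixes wrap across the origin.
# For a "+" insertion at 1-based position p the suffix is genome[p .. p+k-1];
# for a "-" insertion it is the reverse complement of genome[p-k+1 .. p], so
# p is always the first genomic base after the transposon junction in the
# orientation of the read.
siteReadSequences <- function(library, genome, config) {
  k <- config@readLength - config@tagLength
  L <- genomeLength(genome)
  gseq <- as.character(genomeSequence(genome))
  ext <- paste0(gseq, substr(gseq, 1L, min(k - 1L, L)))
  if (nchar(ext) < L + k - 1L)  # genome shorter than one read suffix
    ext <- paste0(strrep(gseq, ceiling((L + k) / L)))
  ins <- insertions(library)
  pos <- start(ins)
  fwd <- as.character(strand(ins)) == "+"
  suff <- character(length(ins))
  if (any(fwd))
    suff[fwd] <- substring(ext, pos[fwd], pos[fwd] + k - 1L)
  if (any(!fwd)) {
    s0 <- (pos[!fwd] - k) %% L + 1L
    suff[!fwd] <- as.character(reverseComplement(
      DNAStringSet(substring(ext, s0, s0 + k - 1L))))
  }
  paste0(config@tagSequence, suff)
}

#' Generate tagged sequencing reads from a mutant library
#'
#' Draws `depthPerSample` reads multinomially over the library's
#' insertions in proportion to abundance. Every read is the transposon tag
#' followed by the genomic sequence downstream of the junction in the
#' insertion's orientation, `readLength` bp in total; the chromosome is
#' circular, so reads near the origin wrap rather than truncate. Base
#' quality is constant (no sequencing-error model).
#'
#' @param library a [MutantLibrary] (abundances need not be normalised).
#' @param genome the [TnGenome] the library was built on.
#' @param config a [SimConfig] supplying read geometry and depth.
#' @param seed RNG seed for the multinomial draw.
#' @param as return type: a [Biostrings::DNAStringSet] (default) or a
#'   plain character vector.
#' @return Reads in the requested representation, in library-site order.
#' @examples
#' cfg <- simConfig(nGenes = 2, depthPerSample = 100, seed = 1)
#' g <- simulateGenome(cfg)
#' lib <- simulateLibrary(g, cfg)
#' reads <- generateReads(lib, g, cfg)
#' @export
generateReads <- function(library, genome, config, seed = config@seed,
                          as = c("DNAStringSet", "character")) {
  validObject(config)
  as <- match.arg(as)
  ins <- insertions(library)
  if (!length(ins)) stop("cannot generate reads from an empty library")
  if (sum(ins$abundance) <= 0) stop("library has zero total abundance")
  counts <- withSeed(seed,
    rmultinom(1L, config@depthPerSample, ins$abundance)[, 1L])
  reads <- rep(siteReadSequences(library, genome, config), counts)
  if (as == "character") reads else DNAStringSet(reads)
}

#' Deterministic fitness assignment for a simulated screen
#'
#' Assigns ground-truth effects to genes for the simulated selection:
#' after skipping essential genes, the first `nSusceptibility`
#' non-essential genes become susceptibility genes (insertion mutants
#' expand, `log2 w = log2wSus` per generation) and the next `nResistance`
#' become resistance genes (mutants depleted, `log2 w = log2wRes`); all
#' other genes are neutral. The default per-generation effects of
#' +4/3 and -4/3 put the design log2 fold change at +/-4 for the weakest
#' replicate selection (3 generations) and larger for the others.
#'
#' @param genome a [TnGenome].
#' @param nSusceptibility,nResistance numbers of effect genes.
#' @param log2wSus,log2wRes per-generation log2 fitness of the two
#'   effect classes.
#' @return A list with `fitness` (a [FitnessMap]) and `truth` (data.frame
#'   of gene_id, class, w, essential).
#' @examples
#' g <- simulateGenome(simConfig(nGenes = 20, seed = 1))
#' screenFitness(g, nSusceptibility = 2, nResistance = 1)$truth[1:5, ]
#' @export
screenFitness <- function(genome, nSusceptibility = 20L, nResistance = 10L,
                          log2wSus = 4 / 3, log2wRes = -4 / 3) {
  genes <- geneRanges(genome)
  nonEss <- genes$gene_id[!genes$essential]
  if (length(nonEss) < nSusceptibility + nResistance)
    stop("not enough non-essential genes for the requested effects")
  sus <- nonEss[seq_len(nSusceptibility)]
  res <- nonEss[nSusceptibility + seq_len(nResistance)]
  w <- setNames(rep(1, length(genes$gene_id)), genes$gene_id)
  w[sus] <- 2^log2wSus
  w[res] <- 2^log2wRes
  cls <- rep("neutral", length(genes))
  cls[genes$gene_id %in% sus] <- "susceptibility"
  cls[genes$gene_id %in% res] <- "resistance"
  cls[genes$essential] <- "essential"
  list(fitness = fitnessMap(w),
       truth = data.frame(gene_id = genes$gene_id, class = cls, w = unname(w),
                          essential = genes$essential))
}

#' Simulate a complete phage-selection screen
#'
#' Runs the whole generative design: genome, saturating library, one
#' untreated control plus one selected condition per entry of
#' `config@generations` (the default four replicates are low/high dose at
#' 3 h and 5 h, encoded as effective selection generations), and tagged
#' reads for every sample. Seeds for each stage are derived
#' deterministically from `seed`, so the full screen is reproducible.
#'
#' @param config a [SimConfig].
#' @param fitness a [FitnessMap], or `NULL` for the default
#'   [screenFitness()] assignment.
#' @param seed base seed (defaults to the config seed).
#' @param readsAs representation of the read vectors ("DNAStringSet" or
#'   "character"; character is faster for in-memory pipelines).
#' @return A list with elements `genome`, `library`, `fitness`, `truth`
#'   (NULL unless the default fitness was used), `selected` (list of
#'   post-selection [MutantLibrary] objects) and `reads` (named list:
#'   `control`, `sel_1` ... `sel_r`).
#' @examples
#' sim <- simulateScreen(simConfig(nGenes = 12, depthPerSample = 2000,
#'                                 seed = 3))
#' names(sim$reads)
#' @export
simulateScreen <- function(config, fitness = NULL, seed = config@seed,
                           readsAs = "DNAStringSet") {
  genome <- simulateGenome(config, seed = seed)
  library <- simulateLibrary(genome, config, seed = seed + 1L)
  truth <- NULL
  if (is.null(fitness)) {
    # default effect set: the study design of 20 susceptibility and 10
    # resistance genes among 200 (10% and 5%), scaled down by those
    # proportions on smaller test genomes
    n <- length(geneRanges(genome))
    sf <- screenFitness(genome,
                        nSusceptibility = min(20L, as.integer(round(n * 0.10))),
                        nResistance = min(10L, as.integer(round(n * 0.05))))
    fitness <- sf$fitness
    truth <- sf$truth
  }
  reads <- list(control = generateReads(library, genome, config,
                                        seed = seed + 100L, as = readsAs))
  selected <- list()
  for (r in seq_along(config@generations)) {
    sel <- applySelection(library, genome, fitness, config@generations[r])
    selected[[paste0("sel_", r)]] <- sel
    reads[[paste0("sel_", r)]] <-
      generateReads(sel, genome, config, seed = seed + 100L + r,
                    as = readsAs)
  }
  list(genome = genome, library = library, fitness = fitness,
       truth = truth, selected = selected, reads = reads, config = config)
}
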