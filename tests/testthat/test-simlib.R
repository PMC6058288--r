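test_that("genome layout alternates intergenic and gene blocks", {
  cfg <- simConfig(nGenes = 2, geneLength = 600, intergenicLength = 100,
                   seed = 1)
  g <- simulateGenome(cfg)
  expect_equal(genomeLength(g), 1500L)
  gr <- geneRanges(g)
  expect_equal(GenomicRanges::start(gr), c(101L, 801L))
  expect_equal(GenomicRanges::end(gr), c(700L, 1400L))
  expect_equal(gr$gene_id, c("gene_0001", "gene_0002"))

  empty <- simulateGenome(simConfig(nGenes = 0, intergenicLength = 4700,
                                    seed = 1))
  expect_equal(genomeLength(empty), 4700L)
  expect_length(geneRanges(empty), 0L)
})

test_that("essential flags are assigned deterministically to leading genes", {
  g <- simulateGenome(simConfig(nGenes = 10, essentialFraction = 0.25,
                                seed = 3))
  expect_equal(geneRanges(g)$essential,
               c(rep(TRUE, 3), rep(FALSE, 7)))  # ceiling(10 * 0.25) = 3
})

test_that("identical config and seed reproduce the screen byte for byte", {
  cfg <- smallConfig(depthPerSample = 500L)
  s1 <- simulateScreen(cfg, readsAs = "character")
  s2 <- simulateScreen(cfg, readsAs = "character")
  expect_identical(as.character(genomeSequence(s1$genome)),
                   as.character(genomeSequence(s2$genome)))
  expect_identical(s1$reads, s2$reads)
  f1 <- tempfile(); f2 <- tempfile()
  writeReadsFastq(s1$reads$control, f1)
  writeReadsFastq(s2$reads$control, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("library saturation matches the target insertion density", {
  # mean UIS over 200 seeds on a 4700-bp gene-free genome at 1/47 bp
  # should be ~Poisson(100); compare against the analytic mean via the
  # Monte-Carlo standard error
  cfg <- simConfig(nGenes = 0, intergenicLength = 4700,
                   insertionDensity = 47, seed = 1)
  g <- simulateGenome(cfg)
  n <- vapply(seq_len(200), function(s)
    uis(simulateLibrary(g, cfg, seed = s)), integer(1))
  sem <- stats::sd(n) / sqrt(length(n))
  # closed-form expectation including duplicate collapse over the
  # 2 * 4700 (position, strand) slots: E[u] = S(1 - (1 - p/S)^L)
  expected <- 9400 * (1 - (1 - (1 / 47) / 9400)^4700)  # ~= 99.47
  expect_lt(abs(mean(n) - expected), 3 * sem)
  expect_lt(abs(mean(n) - 100), 3)
})

test_that("insertions never land in essential genes", {
  g <- handGenome(essential = c(TRUE, FALSE))
  cfg <- smallConfig()
  for (s in 1:5) {
    lib <- simulateLibrary(g, cfg, seed = s)
    ess <- geneRanges(g)[geneRanges(g)$essential]
    expect_equal(sum(GenomicRanges::countOverlaps(insertions(lib), ess,
                                                  ignore.strand = TRUE)), 0L)
  }
  # a genome that is one big essential gene yields an empty library
  set.seed(9)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 470, TRUE), collapse = "")
  allEss <- tnGenome(seq1, GenomicRanges::GRanges("chr",
    IRanges::IRanges(1, 470), gene_id = "only", essential = TRUE))
  expect_equal(uis(simulateLibrary(allEss, cfg, seed = 1)), 0L)
})

test_that("selection multiplies abundance by w^generations and renormalises", {
  g <- handGenome()
  lib <- handLibrary(g, pos = c(150L, 300L, 900L), strand = c("+", "-", "+"))
  # geneA spans 101-700, geneB 801-1400; sites 1 and 2 in geneA
  sel <- applySelection(lib, g, fitnessMap(c(geneA = 2)), generations = 3)
  ab <- insertions(sel)$abundance
  expect_equal(sum(ab), 1)
  expect_equal(ab[1] / ab[3], 8)  # 2^3 relative gain
  expect_equal(ab[1], ab[2])

  neutral <- applySelection(lib, g, fitnessMap(), generations = 7)
  expect_equal(insertions(neutral)$abundance, rep(1 / 3, 3))

  lethal <- applySelection(lib, g, fitnessMap(c(geneA = 0)), generations = 1)
  expect_equal(insertions(lethal)$abundance[1:2], c(0, 0))
})

test_that("reads carry the tag, the right suffix length and exact depth", {
  cfg <- smallConfig(depthPerSample = 1000L)
  sim <- simulateScreen(cfg, fitness = fitnessMap(), readsAs = "character")
  reads <- sim$reads$control
  expect_length(reads, 1000L)
  expect_true(all(nchar(reads) == cfg@readLength))
  expect_true(all(startsWith(reads, cfg@tagSequence)))
  expect_true(all(nchar(substr(reads, cfg@tagLength + 1L, 50L)) == 40L))
})

test_that("a single-insertion library emits identical reads", {
  g <- handGenome()
  lib <- handLibrary(g, pos = 250L)
  cfg <- smallConfig(depthPerSample = 50L)
  reads <- generateReads(lib, g, cfg, as = "character")
  expect_length(unique(reads), 1L)
})

test_that("reads wrap across the origin of the circular chromosome", {
  g <- handGenome()
  L <- genomeLength(g)
  cfg <- smallConfig(depthPerSample = 10L)
  gseq <- as.character(genomeSequence(g))
  # forward insertion at the last base: suffix = last base + first 39
  fwd <- generateReads(handLibrary(g, pos = L), g, cfg, as = "character")[1]
  expect_equal(substr(fwd, 11, 50),
               paste0(substr(gseq, L, L), substr(gseq, 1, 39)))
  # reverse insertion at base 5: suffix = revcomp of bases (L-34..L, 1..5)
  rev <- generateReads(handLibrary(g, pos = 5L, strand = "-"), g, cfg,
                       as = "character")[1]
  region <- paste0(substr(gseq, L - 34, L), substr(gseq, 1, 5))
  expect_equal(substr(rev, 11, 50), as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(region))))
})

test_that("read share fold change tracks t * log2(w) for a rare mutant", {
  # one susceptibility gene among 50 keeps the compositional penalty small,
  # so the expected logFC of its read share is close to t*log2(w) = 3
  cfg <- simConfig(nGenes = 50, geneLength = 300, intergenicLength = 100,
                   essentialFraction = 0, depthPerSample = 100000L,
                   generations = 3, seed = 17)
  g <- simulateGenome(cfg)
  lib <- simulateLibrary(g, cfg)
  fit <- fitnessMap(c(gene_0007 = 2))
  sel <- applySelection(lib, g, fit, generations = 3)
  idx <- genomeIndex(g, k = cfg@readLength - cfg@tagLength)
  spec <- tagSpec(cfg@tagSequence)
  profC <- processReads(generateReads(lib, g, cfg, seed = 1,
                                      as = "character"), g, spec, idx)
  profS <- processReads(generateReads(sel, g, cfg, seed = 2,
                                      as = "character"), g, spec, idx)
  gct <- flagUnassayable(geneCountTable(list(ctrl = profC, sel = profS), g),
                         "ctrl")
  res <- compareSamples(gct, "sel", "ctrl")
  expect_lt(abs(res$logFC[res$gene_id == "gene_0007"] - 3), 0.2)
})
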