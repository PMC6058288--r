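test_that("sites are assigned to genes by inclusive interval containment", {
  g <- handGenome()  # geneA 101..700, geneB 801..1400
  prof <- handProfile(1500, pos = c(101L, 701L, 300L),
                      strand = c("+", "+", "-"), count = c(1L, 1L, 7L))
  tab <- countGeneReads(prof, g)
  a <- tab[tab$gene_id == "geneA", ]
  expect_equal(a$read_count, 8L)       # first base included, 701 excluded
  expect_equal(a$insertion_sites, 2L)
  expect_equal(tab[tab$gene_id == "geneB", ]$read_count, 0L)
  expect_equal(attr(tab, "intergenic_reads"), 1L)
  expect_equal(attr(tab, "intergenic_sites"), 1L)
})

test_that("gene plus intergenic counts conserve every mapped read", {
  cfg <- smallConfig(depthPerSample = 3000L)
  sim <- simulateScreen(cfg, readsAs = "character")
  prof <- processReads(sim$reads$sel_1, sim$genome,
                       tagSpec(cfg@tagSequence))
  tab <- countGeneReads(prof, sim$genome)
  expect_equal(sum(tab$read_count) + attr(tab, "intergenic_reads"),
               readStats(prof)[["mapped"]])
  expect_equal(sum(tab$insertion_sites) + attr(tab, "intergenic_sites"),
               uis(prof))
})

test_that("assayability uses the strict fewer-than-10-control-reads rule", {
  g <- handGenome()
  mk <- function(nA) handProfile(1500, pos = c(150L, 900L),
                                 strand = c("+", "+"),
                                 count = c(nA, 50L))
  for (case in list(list(n = 9L, ok = FALSE), list(n = 10L, ok = TRUE),
                    list(n = 1L, ok = FALSE))) {
    gct <- geneCountTable(list(control = mk(case$n)), g)
    gct <- flagUnassayable(gct, "control")
    expect_equal(assayable(gct)[1], case$ok)
  }
  # a gene with zero control reads is unassayable
  noA <- handProfile(1500, pos = 900L, strand = "+", count = 50L)
  gct <- flagUnassayable(geneCountTable(list(control = noA), g), "control")
  expect_false(assayable(gct)[1])
  expect_error(flagUnassayable(gct, "control", minReads = 0L), "minReads")
})

test_that("library summary reports UIS and bp per insertion", {
  g <- handGenome()
  prof <- handProfile(1500, pos = c(10L, 20L), strand = c("+", "-"),
                      count = c(5L, 1L))
  s <- librarySummary(prof, g)
  expect_equal(s$uis, 2L)
  expect_equal(s$bp_per_insertion, 750)
  empty <- handProfile(1500, pos = integer(0), strand = character(0),
                       count = integer(0))
  expect_error(librarySummary(empty, g), "empty")
})

test_that("simulated libraries hit ~47 bp per insertion", {
  cfg <- simConfig(nGenes = 0, intergenicLength = 470000,
                   insertionDensity = 47, seed = 2)
  g <- simulateGenome(cfg)
  bp <- vapply(1:5, function(s) {
    lib <- simulateLibrary(g, cfg, seed = s)
    genomeLength(g) / uis(lib)
  }, numeric(1))
  expect_lt(abs(mean(bp) - 47), 2)
})

test_that("essential genes in a simulated screen are always unassayable", {
  cfg <- smallConfig(essentialFraction = 0.2, depthPerSample = 20000L)
  sim <- simulateScreen(cfg, readsAs = "character")
  prof <- processReads(sim$reads$control, sim$genome,
                       tagSpec(cfg@tagSequence))
  gct <- flagUnassayable(geneCountTable(list(control = prof), sim$genome),
                         "control")
  ess <- geneRanges(sim$genome)$essential
  expect_true(all(!assayable(gct)[ess]))
})

test_that("zero-insertion probability follows the Poisson zero class", {
  expect_equal(zeroInsertionProbability(0, 47), 1)
  p600 <- zeroInsertionProbability(600, 47)
  expect_equal(p600, exp(-600 / 47))
  expect_lt(p600, 0.001)
  # strictly decreasing in gene length, increasing in density spacing
  L <- seq(0, 2000, by = 100)
  expect_true(all(diff(zeroInsertionProbability(L, 47)) < 0))
  d <- seq(10, 200, by = 10)
  expect_true(all(diff(zeroInsertionProbability(600, d)) > 0))
  expect_error(zeroInsertionProbability(600, 0), "bpPerInsertion")
})

test_that("binomial placement form matches enumeration and the Poisson form", {
  # exhaustive oracle: two insertions placed independently on a 10-bp
  # genome; count placements with neither inside the 4-bp gene
  placements <- expand.grid(a = 1:10, b = 1:10)
  inGene <- function(p) p >= 4 & p <= 7
  frac <- mean(!inGene(placements$a) & !inGene(placements$b))
  expect_equal(frac, 0.36)
  expect_equal(zeroInsertionProbabilityExact(4, 10, 2), frac)
  # Poisson and binomial forms agree within 1% once L is truly small
  # relative to G (the relative gap is ~ exp(N (L/G)^2 / 2) - 1)
  N <- 10000; d <- 47; G <- N * d
  expect_lt(abs(zeroInsertionProbabilityExact(600, G, N) /
                  zeroInsertionProbability(600, d) - 1), 0.01)
})
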