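tag10 <- "CTGTCTCTTA"

test_that("tag verification trims exact prefixes and rejects others", {
  spec <- tagSpec(tag10)
  read <- paste0(tag10, strrep("ACGT", 10))
  out <- checkAndTrimTag(read, spec)
  expect_equal(out$status[1], factor("tagged",
               levels = c("tagged", "tag_mismatch", "too_short")))
  expect_equal(nchar(out$trimmed[1]), 40L)

  oneOff <- paste0("ATGTCTCTTA", strrep("ACGT", 10))
  expect_equal(as.character(checkAndTrimTag(oneOff, spec)$status),
               "tag_mismatch")
  expect_equal(as.character(
    checkAndTrimTag(oneOff, tagSpec(tag10, maxMismatches = 1))$status),
    "tagged")
  # a read no longer than the tag gets its own reason code
  expect_equal(as.character(checkAndTrimTag("CTGTCTCTTA", spec)$status),
               "too_short")
})

test_that("exact placement maps reads to their generating site and strand", {
  g <- handGenome()
  gseq <- as.character(genomeSequence(g))
  idx <- genomeIndex(g, k = 40)
  # forward read from position 1234
  m <- mapReads(substr(gseq, 1234, 1273), idx)
  expect_equal(as.character(m$status), "mapped")
  expect_equal(m$position, 1234L)
  expect_equal(m$strand, "+")
  # reverse-strand read: revcomp of bases 561..600 came from a junction
  # whose forward-frame coordinate is the last matched base, 600
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gseq, 561, 600))))
  m2 <- mapReads(rc, idx)
  expect_equal(as.character(m2$status), "mapped")
  expect_equal(m2$position, 600L)
  expect_equal(m2$strand, "-")
})

test_that("repeated k-mers are ambiguous and foreign k-mers unmapped", {
  set.seed(4)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  dup <- paste0(base, substr(base, 1, 40))  # bases 1-40 occur twice
  g <- tnGenome(dup, GenomicRanges::GRanges(gene_id = character(0),
                                            essential = logical(0)))
  idx <- genomeIndex(g, k = 40)
  expect_equal(as.character(mapReads(substr(base, 1, 40), idx)$status),
               "ambiguous")
  foreign <- strrep("AC", 20)  # palindrome-free probe absent by construction
  if (!grepl(foreign, dup, fixed = TRUE))
    expect_equal(as.character(mapReads(foreign, idx)$status), "unmapped")
})

test_that("round-trip: every simulated read maps back to its true site", {
  cfg <- smallConfig(depthPerSample = 2000L)
  sim <- simulateScreen(cfg, fitness = fitnessMap(), readsAs = "character")
  prof <- processReads(sim$reads$control, sim$genome,
                       tagSpec(cfg@tagSequence))
  st <- readStats(prof)
  expect_equal(st[["mapped"]], 2000L)
  expect_equal(st[["ambiguous"]] + st[["unmapped"]] + st[["rejected"]], 0L)
  # observed sites are a subset of the library's true junctions
  truthKey <- paste(GenomicRanges::start(insertions(sim$library)),
                    as.character(GenomicRanges::strand(insertions(sim$library))))
  obsKey <- paste(GenomicRanges::start(insertionSites(prof)),
                  as.character(GenomicRanges::strand(insertionSites(prof))))
  expect_true(all(obsKey %in% truthKey))
})

test_that("profiles aggregate by (position, strand) and conserve reads", {
  m <- data.frame(position = c(10L, 10L, 10L, NA, NA),
                  strand = c("+", "+", "-", NA, NA),
                  status = factor(c("mapped", "mapped", "mapped",
                                    "ambiguous", "unmapped"),
                                  levels = c("mapped", "ambiguous",
                                             "unmapped")))
  prof <- buildInsertionProfile(m, genomeLength = 100,
                                nReadsTotal = 7, nReadsTagged = 5)
  s <- insertionSites(prof)
  expect_equal(length(s), 2L)  # same position, opposite strands: two UIS
  expect_equal(s$count[as.character(GenomicRanges::strand(s)) == "+"], 2L)
  st <- readStats(prof)
  expect_equal(st[["total"]],
               st[["rejected"]] + st[["unmapped"]] + st[["ambiguous"]] +
                 st[["mapped"]])
  expect_equal(sum(s$count), st[["mapped"]])

  emptyProf <- buildInsertionProfile(
    data.frame(position = integer(0), strand = character(0),
               status = factor(character(0),
                               levels = c("mapped", "ambiguous",
                                          "unmapped"))),
    genomeLength = 100)
  expect_equal(uis(emptyProf), 0L)
  expect_equal(readStats(emptyProf)[["mapped"]], 0L)
})

test_that("mixed-quality input is partitioned exactly", {
  g <- handGenome()
  gseq <- as.character(genomeSequence(g))
  good <- paste0(tag10, substr(gseq, 101, 140))
  badTag <- paste0("AAAAAAAAAA", substr(gseq, 101, 140))
  alien <- paste0(tag10, strrep("AC", 20))
  reads <- c(rep(good, 3), badTag, alien)
  prof <- processReads(reads, g, tagSpec(tag10))
  st <- readStats(prof)
  expect_equal(st[["total"]], 5L)
  expect_equal(st[["rejected"]], 1L)
  expect_equal(st[["mapped"]], 3L)
  expect_equal(st[["mapped"]] + st[["ambiguous"]] + st[["unmapped"]],
               st[["tagged"]])
})
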