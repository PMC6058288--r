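test_that("lysis grades encode full, partial and no clearing", {
  expect_equal(gradeLysis(c(TRUE, TRUE, TRUE))$grade, 2L)
  none <- gradeLysis(c(FALSE, FALSE, FALSE))
  expect_equal(none$grade, 0L)
  expect_equal(none$depth, -1L)
  part <- gradeLysis(c(TRUE, FALSE, FALSE))
  expect_equal(part$grade, 1L)
  expect_equal(part$depth, 0L)
  expect_error(gradeLysis(logical(0)), "empty")
})

test_that("clearing one more dilution step never lowers the grade", {
  set.seed(2)
  for (i in 1:50) {
    s <- runif(6) < 0.5
    g1 <- gradeLysis(s)$grade
    off <- which(!s)
    if (!length(off)) next
    s2 <- s
    s2[sample(off, 1)] <- TRUE
    expect_gte(gradeLysis(s2)$grade, g1)
  }
})

test_that("profile comparison is ordinal and antisymmetric", {
  wt <- lysisProfile("WT", c(TP1 = 0, TP2 = 1, TP3 = 2, TP4 = 1))
  ko <- lysisProfile("KO", c(TP1 = 2, TP2 = 0, TP3 = 2, TP4 = 1))
  cmp <- compareProfiles(wt, ko)
  expect_equal(as.character(cmp$change),
               c("increased", "decreased", "no_change", "no_change"))
  expect_equal(as.character(cmp$ceiling), c("down", "none", "up", "none"))
  # swapping strains maps increased <-> decreased
  rev <- compareProfiles(ko, wt)
  expect_equal(as.character(rev$change),
               c("decreased", "increased", "no_change", "no_change"))
  expect_error(compareProfiles(wt, lysisProfile("KO2", c(TPX = 1))),
               "panel")
})

test_that("concordance tallies partition the phage panel", {
  wt <- lysisProfile("WT", c(TP1 = 2, TP2 = 1, TP3 = 0, TP4 = 1))
  kos <- list(
    up = lysisProfile("up", c(TP1 = 2, TP2 = 2, TP3 = 0, TP4 = 0)),
    down = lysisProfile("down", c(TP1 = 1, TP2 = 1, TP3 = 0, TP4 = 1)))
  preds <- data.frame(strain_id = c("up", "down"),
                      predicted_change = c("increased_lysis",
                                           "decreased_lysis"))
  out <- concordance(preds, wt, kos)
  tot <- out$n_agree + out$n_oppose + out$n_no_change + out$n_unobservable
  expect_equal(tot, c(4L, 4L))
  up <- out[out$strain_id == "up", ]
  # TP1: wt maximal, no change -> unobservable; TP2 agree; TP3 no change
  # (wt minimal does not block an increase); TP4 oppose
  expect_equal(up$n_agree, 1L)
  expect_equal(up$n_oppose, 1L)
  expect_equal(up$n_no_change, 1L)
  expect_equal(up$n_unobservable, 1L)
  down <- out[out$strain_id == "down", ]
  # TP1 agree; TP3 unobservable (wt already fully resistant)
  expect_equal(down$n_agree, 1L)
  expect_equal(down$n_unobservable, 1L)
  expect_error(concordance(preds[1, , drop = FALSE], wt, kos), "missing")
})

test_that("transcribed knockout outcomes reproduce the reported directions", {
  grid <- readLysisGrid(system.file("extdata",
                                    "lysis_changes_transcribed.tsv",
                                    package = "phageTnScreen"))
  wt <- grid$WT
  preds <- data.frame(strain_id = c("fcl", "waaL", "sspA"),
                      predicted_change = "increased_lysis")
  out <- concordance(preds, wt, grid[c("fcl", "waaL", "sspA")])
  rownames(out) <- out$strain_id
  # all three knockouts show the predicted increase on the representative
  # mid-panel phage; fcl and waaL additionally convert TP16
  expect_gte(out["fcl", "n_agree"], 2L)
  expect_gte(out["waaL", "n_agree"], 2L)
  expect_equal(out["sspA", "n_agree"], 1L)
  # opposite-direction effects: fcl on TP3, waaL and sspA on TP14
  expect_equal(out["fcl", "n_oppose"], 1L)
  expect_equal(out["waaL", "n_oppose"], 1L)
  expect_equal(out["sspA", "n_oppose"], 1L)
  # sspA does not convert TP16: observable no-change, not unobservable
  expect_equal(out["sspA", "n_no_change"], 1L)
  # phages the wild type already fully lyses are unobservable for an
  # increased-lysis prediction
  expect_gte(out["sspA", "n_unobservable"], 2L)
})
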