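# Independent oracles used by the statistical tests.

# two-sided conditional binomial p-value by plain choose() arithmetic;
# shares no code with binomialCountTest()
oracleBinomP <- function(s, c, piSel) {
  n <- s + c
  if (n == 0) return(1)
  k <- 0:n
  pmf <- choose(n, k) * piSel^k * (1 - piSel)^(n - k)
  min(1, sum(pmf[pmf <= pmf[s + 1] * (1 + 1e-9)]))
}

# brute-force BH step-up, independent of stats::p.adjust
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}
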