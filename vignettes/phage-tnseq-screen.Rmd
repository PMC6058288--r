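---
title: "Modelling and analysing a transposon-library phage selection screen"
author: "phageTnScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing a transposon-library phage selection screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The experiment being modelled

A saturating transposon (Tn5) mutant library of a bacterial strain is
grown with and without a lytic bacteriophage. Sequencing outward from
the transposon junction (TraDIS: every read starts with a fixed
transposon tag, followed by the genomic sequence downstream of the
insertion point) quantifies each insertion mutant in the pool. Genes
whose insertion mutants *expand* under phage selection are
**susceptibility genes**: the intact gene normally aids phage killing
(e.g. a receptor), so losing it protects the cell. Genes whose mutants
are *depleted* are **resistance genes**: the intact gene normally
protects the cell, so losing it makes the mutant easier to kill.

The analysis is count-based. For each gene, reads whose junctions fall
inside the gene are summed per sample; the change between a selected
sample and the untreated control is summarised as the log2 fold change
(logFC) of counts per million (CPM), with an exact conditional binomial
p-value and a Benjamini–Hochberg q-value. A gene is called only when it
passes |logFC| ≥ 2, q < 0.01 and p < 0.05 in **all** replicate
selections (by design four: two phage doses at two exposure times), and
its reported effect is the mean logFC over the replicates.

# The generative model

`simulateScreen()` produces a complete screen with known ground truth:

1. **Genome** (`simulateGenome`): alternating intergenic and gene blocks
   with uniform random bases. Defaults: 200 genes of 600 bp separated by
   150-bp intergenic blocks, i.e. a 150,150-bp chromosome — a
   deliberately scaled-down stand-in for a ~5 Mb enterobacterial
   chromosome that keeps a full multi-replicate screen runnable in
   seconds. The first `ceiling(nGenes * essentialFraction)` genes
   (default 5%) are flagged essential.
2. **Library** (`simulateLibrary`): candidate insertion sites are drawn
   uniformly with expected count `genome length / 47` (the saturating
   density of one insertion per 47 bp), each with a random orientation;
   the same position in opposite orientations is two distinct mutants.
   Sites inside essential genes are rejected — those mutants are never
   recovered — rather than zeroed afterwards. Because of this rejection,
   the *realised* genome-wide density under 5% essential content is
   ~50 bp per insertion even though the candidate density is 1/47.
3. **Selection** (`applySelection`): deterministic exponential growth.
   Each insertion's abundance is multiplied by `w^t`, where `w` is the
   per-generation relative fitness of the host gene's mutants and `t`
   the effective number of selection generations, then renormalised to
   sum to one. Dose and exposure time both scale kill-off, so the four
   replicates are encoded as generations `c(3, 5, 4.5, 7.5)`: the two
   exposure times (3 h and 5 h) at the low dose, and the same two times
   at a 1.5× stronger high dose. The source experiment reports its two
   doses inconsistently in different places (1 µl vs 10 µl, plus
   200 µl), which is one reason dose is treated as an abstract
   selection-strength parameter rather than a titre.
4. **Reads** (`generateReads`): the sample's depth (default 2×10^5
   reads) is drawn multinomially over insertions by abundance. Each read
   is the 10-bp transposon tag followed by 40 bp of genomic sequence
   downstream of the junction in the insertion's orientation (50-bp
   single-end geometry). The chromosome is treated as circular so
   junctions near the origin wrap instead of truncating. Base quality is
   constant: the analysed pipeline maps raw reads exactly, so a
   sequencing-error model would only dilute what the tests measure.

Default effect sizes (`screenFitness`): 20 susceptibility genes with
`log2 w = +4/3` and 10 resistance genes with `log2 w = -4/3`, assigned
deterministically to the first non-essential genes. The design logFC of
an effect gene is therefore ±4 at the weakest replicate (t = 3) and
larger in the others. Anchoring at the weakest replicate matters because
the consensus requires every replicate to pass.

## The compositional penalty

Relative abundances must sum to one, so when susceptibility mutants
expand 2^4–2^10-fold, every *other* mutant's share shrinks. At the
strongest default replicate (t = 7.5) neutral genes show an apparent
logFC near −6; at the weakest (t = 3) only about −1.1. Single
comparisons at strong selection would therefore miscall neutral genes as
resistance genes — it is the all-replicates intersection, anchored by
the weak replicate, that keeps the false-call rate at zero in the
simulated screens. This mirrors the real experiment's motivation for
intersecting replicates rather than pooling them.

## What the simulator does not model

No lysogeny, adsorption kinetics or phage evolution; no PCR duplicates,
GC bias, insertion-site sequence preference (Tn5's mild AT bias is
ignored) or sequencing errors; no biological replicate dispersion beyond
multinomial sampling. Passing tests therefore show that the pipeline's
logic and statistics recover clean multinomial signals, not that the
statistics are robust to overdispersed real libraries — on real data the
exact binomial test is anti-conservative, which is one reason real
analyses use replicate-aware tools. The intersect-across-replicates rule
absorbs some of that risk by construction.

# The read-to-call pipeline

* **Tag verification** (`checkAndTrimTag`): a read is kept when its
  prefix matches the tag within `maxMismatches` Hamming mismatches.
  The default is 0 (exact): the experimental protocol guarantees the
  tag's presence, and the tolerance is configurable for noisier input.
* **Mapping** (`genomeIndex`, `mapReads`): exact placement of the 40-bp
  trimmed read against all k-mers of the circular genome, both strands.
  Reads matching more than one location are discarded as ambiguous
  (random assignment would create phantom insertion sites); this, not a
  full aligner, is appropriate because simulated reads are error-free,
  and externally mapped real data can enter via insertion-profile TSVs.
  The insertion coordinate convention is the first genomic base after
  the junction in the forward reference frame — the match start on the
  plus strand, the match end on the minus strand — and the same
  coordinate hit in both orientations counts as two unique insertion
  sites (UIS).
* **Gene counting** (`geneCountTable`): a site belongs to a gene when it
  lies within the annotated interval, regardless of strand on either
  side — an insertion disrupts a gene in any orientation. No trimming of
  gene termini is applied; the full span is counted. Sites outside every
  gene accumulate in a per-sample intergenic bucket so reads stay
  conserved: gene counts + intergenic = mapped.
* **Assayability** (`flagUnassayable`): genes with fewer than 10 reads
  in the untreated control cannot be measured (in practice: essential
  genes, which tolerate no insertions) and are excluded from testing but
  kept in the table. The threshold is inclusive at 10 — exactly 10
  control reads is assayable. `zeroInsertionProbability(600, 47)`
  ≈ 2.9×10⁻⁶ shows why an insertion-free gene of typical length can be
  attributed to essentiality rather than chance at this saturation.
* **Per-gene test** (`binomialCountTest`): conditional on a gene's total
  count n across the two samples, the selected-sample count is
  Binomial(n, π) under the null, with π the selected library's share of
  the summed library sizes. Two-sided p-values use the
  minimum-likelihood rule (sum of all outcome probabilities not
  exceeding the observed one, ties included at relative tolerance
  1e-12). The original analysis delegated testing to an external
  toolchain whose exact procedure is not specified; this package defines
  its test explicitly so that every number it produces is reproducible
  from first principles, and validates it against exhaustive enumeration
  and `stats::binom.test`. FDR control is standard Benjamini–Hochberg
  (`stats::p.adjust`), cross-checked against a brute-force step-up in
  the tests.
* **logFC** (`logFoldChange`): `log2((cpm_sel + 0.5)/(cpm_ctrl + 0.5))`.
  The 0.5 CPM pseudocount is symmetric (swapping samples negates the
  value exactly), keeps zero counts finite, and perturbs a CPM ≥ 100
  gene's logFC by < 0.01.
* **Consensus** (`consensusCalls`): a gene is called only with the same
  sign in all replicates, each replicate passing all three cutoffs;
  the fold-change cutoff is inclusive (≥ 2 / ≤ −2) and the significance
  cutoffs strict (q < 0.01, p < 0.05), with q computed per comparison —
  each replicate must implicate the gene independently. The reported
  effect is the mean logFC over all four comparisons (averaging per
  dose first and then across doses is algebraically identical for four
  values).

# Phenotype confirmation logic

Plaque assays grade a strain against each typing phage on an ordinal
scale: 0 (full resistance, "−"), 1 (partial lysis, "(+)"), 2 (full
lysis, "+"), derived from a spot-dilution series by `gradeLysis()`. A
resistance-gene knockout is predicted to show increased lysis, a
susceptibility-gene knockout decreased lysis. `compareProfiles()` scores
knockout-vs-wild-type changes per phage, and `concordance()` tallies
agreements and oppositions — excluding phages where the wild type is
already at the boundary that blocks the predicted direction (a strain
already fully lysed cannot become observably more susceptible), which
are reported as unobservable rather than as evidence either way. The
packaged lysis grid in `inst/extdata/` is a labelled transcription of
reported knockout outcomes used for regression tests, not measured
plate values.

# Numerical and testing choices

* All containers are Bioconductor types (GRanges, SummarizedExperiment,
  DNAString); coordinates are 1-based inclusive in memory and in GFF3,
  converted from the generators' half-open arithmetic at construction.
* Every stochastic stage takes an explicit seed, and the orchestration
  derives per-stage seeds from one base seed; identical configuration
  and seed give byte-identical FASTQ output.
* Test problem sizes: unit tests use 10–50 gene genomes at depths of
  10³–10⁵ reads; the end-to-end recovery and null-control checks use the
  full default design (200 genes, 150 kb, 2×10⁵ reads × 5 samples)
  over 20 seeds each, chosen to estimate sensitivity, precision and the
  null call rate with Monte-Carlo error well below the margins being
  asserted.
* Degenerate inputs are defined, not accidental: a zero-gene genome is
  a single intergenic block; an all-essential genome yields an empty
  library; an empty library refuses to generate reads; a gene with
  n = 0 total counts gets p = 1.

# Known limitations

Exact-match mapping cannot place reads containing errors, and repeats
longer than the trimmed read length are discarded as ambiguous rather
than resolved. The binomial test treats each comparison's counts as
multinomial draws — adequate for the simulator, anti-conservative for
overdispersed real data. Essentiality is handled only as
non-assayability; no formal essentiality calling (e.g. insertion-index
mixture models) is attempted. The headline gene lists of the original
screen derive from its real sequencing data and are outside what a
desk-scale simulation can or should reproduce.
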