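#' Read and write screen data in standard formats
#'
#' FASTA + GFF3 carry the annotated genome (GFF3 is 1-based inclusive
#' with an `essential=true/false` attribute), FASTQ carries reads, and
#' tab-separated files carry insertion profiles, gene count tables,
#' comparison results and consensus calls. Insertion-profile TSVs use
#' 1-based positions and preserve the read-partition bookkeeping in
#' `#`-comment headers, so a profile round-trips exactly.
#'
#' @name screen-io
NULL

#' @describeIn screen-io write the genome sequence as FASTA.
#' @param genome a [TnGenome].
#' @param path output (or input) file path.
#' @export
writeGenomeFasta <- function(genome, path) {
  x <- DNAStringSet(genomeSequence(genome))
  names(x) <- "chr"
  writeXStringSet(x, path)
  invisible(path)
}

#' @describeIn screen-io write the gene annotation as GFF3 (1-based
#'   inclusive coordinates, `essential=true/false` attribute).
#' @export
writeGenesGff3 <- function(genome, path) {
  g <- geneRanges(genome)
  out <- g
  mcols(out) <- DataFrame(
    type = rep("gene", length(g)),
    ID = g$gene_id,
    essential = ifelse(g$essential, "true", "false"))
  GenomeInfoDb::seqlengths(out) <- genomeLength(genome)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' @describeIn screen-io read a FASTA + GFF3 pair back into a [TnGenome].
#' @param fastaPath,gffPath paths of the genome FASTA and gene GFF3.
#' @export
readTnGenome <- function(fastaPath, gffPath) {
  seq <- readDNAStringSet(fastaPath)[[1L]]
  gr <- rtracklayer::import(gffPath, format = "gff3")
  genes <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   strand = strand(gr),
                   gene_id = gr$ID,
                   essential = tolower(as.character(gr$essential)) == "true")
  tnGenome(seq, genes)
}

#' @describeIn screen-io write reads as FASTQ with constant base quality.
#' @param reads a [Biostrings::DNAStringSet] or character vector.
#' @param quality single quality character applied to every base.
#' @param idPrefix prefix for generated read identifiers.
#' @export
writeReadsFastq <- function(reads, path, quality = "I",
                            idPrefix = "read") {
  if (is.character(reads)) reads <- DNAStringSet(reads)
  names(reads) <- sprintf("%s_%d", idPrefix, seq_along(reads))
  quals <- BStringSet(strrep(quality, Biostrings::width(reads)))
  writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @describeIn screen-io read FASTQ into a [Biostrings::DNAStringSet]
#'   (plain or gzip-compressed).
#' @export
readReadsFastq <- function(path) {
  readDNAStringSet(path, format = "fastq")
}

#' @describeIn screen-io write an [InsertionProfile] as TSV
#'   (`position`, `strand`, `count`; 1-based positions) with bookkeeping
#'   totals in comment headers.
#' @param profile an [InsertionProfile].
#' @export
writeInsertionProfile <- function(profile, path) {
  s <- insertionSites(profile)
  st <- readStats(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# genome_length=%d", genomeLength(profile)),
               sprintf("# n_reads_total=%d", st[["total"]]),
               sprintf("# n_reads_tagged=%d", st[["tagged"]]),
               sprintf("# n_reads_ambiguous=%d", st[["ambiguous"]]),
               sprintf("# n_reads_unmapped=%d", st[["unmapped"]]),
               "position\tstrand\tcount"), con)
  if (length(s))
    writeLines(sprintf("%d\t%s\t%d", start(s),
                       as.character(strand(s)), s$count), con)
  invisible(path)
}

#' @describeIn screen-io read an insertion-profile TSV back. Files
#'   without the bookkeeping headers (e.g. insertion points extracted
#'   from an external mapper) get totals reconstructed from the counts.
#' @export
readInsertionProfile <- function(path, genomeLength = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getNum <- function(key) {
    x <- sub(sprintf("^# %s=", key), "", hdr[startsWith(hdr,
                                                  sprintf("# %s=", key))])
    if (length(x)) as.integer(x[1L]) else NA_integer_
  }
  gl <- getNum("genome_length")
  if (is.na(gl)) gl <- as.integer(genomeLength)
  if (is.na(gl)) stop("genome_length not in file; supply it explicitly")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  dat <- read.delim(text = paste(body, collapse = "\n"),
                    colClasses = c("integer", "character", "integer"))
  nMapped <- sum(dat$count)
  nAmb <- getNum("n_reads_ambiguous")
  nUnm <- getNum("n_reads_unmapped")
  if (is.na(nAmb)) nAmb <- 0L
  if (is.na(nUnm)) nUnm <- 0L
  nTag <- getNum("n_reads_tagged")
  if (is.na(nTag)) nTag <- nMapped + nAmb + nUnm
  nTot <- getNum("n_reads_total")
  if (is.na(nTot)) nTot <- nTag
  sites <- if (nrow(dat))
    GenomicRanges::sort(GRanges("chr", IRanges(dat$position, width = 1L),
                                strand = dat$strand,
                                count = dat$count),
                        ignore.strand = TRUE)
  else GRanges(count = integer(0))
  new("InsertionProfile", sites = sites, genomeLength = gl,
      nReadsTotal = nTot, nReadsTagged = nTag,
      nReadsMapped = as.integer(nMapped), nReadsAmbiguous = nAmb,
      nReadsUnmapped = nUnm)
}

#' @describeIn screen-io write a per-base plot file: one row per genome
#'   base, two columns (forward and reverse read counts), compatible with
#'   common transposon-insertion plotters.
#' @export
writeInsertionPlot <- function(profile, path) {
  L <- genomeLength(profile)
  fwd <- integer(L)
  rev <- integer(L)
  s <- insertionSites(profile)
  plus <- as.character(strand(s)) == "+"
  fwd[start(s)[plus]] <- s$count[plus]
  rev[start(s)[!plus]] <- s$count[!plus]
  writeLines(paste(fwd, rev), path)
  invisible(path)
}

#' @describeIn screen-io write a [TnGeneCounts] as TSV: one row per gene
#'   with read and site counts per sample; per-sample totals in comment
#'   headers.
#' @param table a [TnGeneCounts].
#' @export
writeGeneCountTable <- function(table, path) {
  rd <- rowData(table)
  cd <- colData(table)
  df <- data.frame(gene_id = rd$gene_id, gene_length = rd$gene_length,
                   check.names = FALSE)
  if ("essential" %in% names(rd)) df$essential <- rd$essential
  if ("assayable" %in% names(rd)) df$assayable <- rd$assayable
  for (s in colnames(table)) {
    df[[paste0("reads_", s)]] <- assay(table, "reads")[, s]
    df[[paste0("sites_", s)]] <- assay(table, "sites")[, s]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample=%s mapped=%d intergenic_reads=%d intergenic_sites=%d",
                     rownames(cd), cd$n_reads_mapped,
                     as.integer(cd$intergenic_reads),
                     as.integer(cd$intergenic_sites)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn screen-io read a gene count table TSV back into a
#'   [TnGeneCounts] (without genomic coordinates).
#' @export
readGeneCountTable <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   check.names = FALSE)
  samples <- sub("^reads_", "", grep("^reads_", names(df), value = TRUE))
  reads <- as.matrix(df[paste0("reads_", samples)])
  sites <- as.matrix(df[paste0("sites_", samples)])
  dimnames(reads) <- dimnames(sites) <- list(df$gene_id, samples)
  parse1 <- function(h, key) as.integer(sub(sprintf(".*%s=(\\d+).*", key),
                                            "\\1", h))
  sampleOf <- sub(".*sample=(\\S+).*", "\\1", hdr)
  ord <- match(samples, sampleOf)
  cd <- DataFrame(n_reads_mapped = parse1(hdr[ord], "mapped"),
                  intergenic_reads = parse1(hdr[ord], "intergenic_reads"),
                  intergenic_sites = parse1(hdr[ord], "intergenic_sites"),
                  row.names = samples)
  rd <- DataFrame(gene_id = df$gene_id, gene_length = df$gene_length)
  if ("essential" %in% names(df)) rd$essential <- df$essential
  if ("assayable" %in% names(df)) rd$assayable <- df$assayable
  se <- SummarizedExperiment(assays = list(reads = reads, sites = sites),
                             rowData = rd, colData = cd)
  new("TnGeneCounts", se)
}

#' @describeIn screen-io write a comparison result (`gene_id`, `logFC`,
#'   `p`, `q`) as TSV.
#' @param result a comparison table from [compareSamples()].
#' @export
writeComparison <- function(result, path) {
  write.table(as.data.frame(result[c("gene_id", "logFC", "p", "q")]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn screen-io read a comparison TSV back.
#' @export
readComparison <- function(path) {
  df <- read.delim(path)
  DataFrame(df[c("gene_id", "logFC", "p", "q")])
}

#' @describeIn screen-io write consensus calls as TSV, plus (optionally)
#'   one gene-list file per called class.
#' @param calls a consensus table from [consensusCalls()].
#' @param listPrefix if non-NULL, also write
#'   `<listPrefix>_susceptibility.tsv` and `<listPrefix>_resistance.tsv`
#'   holding the called genes and their mean logFC.
#' @export
writeConsensusCalls <- function(calls, path, listPrefix = NULL) {
  df <- as.data.frame(calls)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(listPrefix)) {
    for (cl in c("susceptibility", "resistance")) {
      sub <- df[df$class == cl, c("gene_id", "mean_logFC")]
      write.table(sub, sprintf("%s_%s.tsv", listPrefix, cl), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' @describeIn screen-io write ground-truth gene effects
#'   (`gene_id`, `class`, `w`, `essential`) as TSV.
#' @param truth truth data.frame from [screenFitness()] /
#'   [simulateScreen()].
#' @export
writeGroundTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn screen-io write a full simulated screen to a directory:
#'   `genome.fasta`, `genes.gff3`, `truth.tsv` and one FASTQ per sample.
#' @param sim result of [simulateScreen()].
#' @param outdir output directory (created if needed).
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeGenomeFasta(sim$genome, file.path(outdir, "genome.fasta"))
  writeGenesGff3(sim$genome, file.path(outdir, "genes.gff3"))
  if (!is.null(sim$truth))
    writeGroundTruth(sim$truth, file.path(outdir, "truth.tsv"))
  for (s in names(sim$reads))
    writeReadsFastq(sim$reads[[s]],
                    file.path(outdir, paste0(s, ".fastq")),
                    idPrefix = s)
  invisible(outdir)
}

# token mapping for lysis grids: 0 <-> "-", 1 <-> "(+)", 2 <-> "+"
lysisToken <- function(grade) c("-", "(+)", "+")[grade + 1L]
lysisGrade <- function(token) {
  g <- match(trimws(token), c("-", "(+)", "+")) - 1L
  if (any(is.na(g))) stop("lysis tokens must be one of -, (+), +")
  g
}

#' @describeIn screen-io write lysis profiles as a strain x phage grid of
#'   `+` / `(+)` / `-` tokens.
#' @param profiles named list of [LysisProfile] objects sharing a panel.
#' @export
writeLysisGrid <- function(profiles, path) {
  panel <- names(profiles[[1L]]@grades)
  rows <- vapply(profiles, function(p) {
    paste(c(p@strainId, lysisToken(p@grades[panel])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("strain", panel), collapse = "\t"), rows), path)
  invisible(path)
}

#' @describeIn screen-io read a lysis grid back into a named list of
#'   [LysisProfile] objects.
#' @export
readLysisGrid <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   comment.char = "#")
  panel <- names(df)[-1L]
  out <- lapply(seq_len(nrow(df)), function(i) {
    lysisProfile(df$strain[i],
                 setNames(lysisGrade(unlist(df[i, -1L])), panel))
  })
  names(out) <- df$strain
  out
}
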