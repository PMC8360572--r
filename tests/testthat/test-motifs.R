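# IUPAC oligo / dyad scanning, enrichment folds, promoter space, TSS
# statistics, merged contigs and catalogs.

dna <- function(...) DNAStringSet(c(...))

test_that("expanding sub-minimum regions pads symmetrically, extra base left", {
  g <- tinyGenome(c(chr1 = 10000L))
  r <- expandMinSize(gr0("chr1", 100, 110, genome = g), 24)
  expect_equal(bed0(r), data.frame(chrom = "chr1", start = 93L, end = 117L))
  # odd deficit: width 13 -> deficit 11 -> 6 left, 5 right
  r2 <- expandMinSize(gr0("chr1", 100, 113, genome = g), 24)
  expect_equal(bed0(r2), data.frame(chrom = "chr1", start = 94L, end = 118L))
  expect_equal(width(expandMinSize(gr0("chr1", 0, 24, genome = g), 24)), 24)
  expect_equal(bed0(expandMinSize(gr0("chr1", 50, 80, genome = g), 24)),
               data.frame(chrom = "chr1", start = 50L, end = 80L))
  # clipped at the chromosome start
  r3 <- expandMinSize(gr0("chr1", 2, 8, genome = g), 24)
  expect_equal(start(r3), 1L)
})

test_that("oligo scanning reports both strands with the S4-style name rule", {
  seqs <- dna(chr1 = paste0(strrep("A", 10), "CGTCA", strrep("A", 10)))
  m <- motifModel("om015", "oligo", "CGTCA")
  hits <- siteRanges(scanMotif(seqs, m))
  expect_equal(bed0(hits), data.frame(chrom = "chr1", start = 10L, end = 15L))
  expect_equal(as.character(strand(hits)), "+")
  expect_equal(names(hits), "om015_CGTCA_CGTCA")
  # reverse-complement occurrence reported on '-' in motif orientation
  seqs2 <- dna(chr1 = paste0(strrep("C", 10), "TGACG", strrep("C", 10)))
  hits2 <- siteRanges(scanMotif(seqs2, m))
  expect_equal(as.character(strand(hits2)), "-")
  expect_equal(mcols(hits2)$matchSeq, "CGTCA")
  # invalid IUPAC character errors at model construction
  expect_error(motifModel("bad", "oligo", "CGTXA"), "IUPAC")
})

test_that("dyad scanning matches left word, spacer range and right word", {
  seqs <- dna(chr1 = paste0("GGTAACCC", strrep("T", 20)))
  m <- motifModel("dy1", "dyad", leftWord = "GGT", rightWord = "CCC",
                  spacerMin = 2, spacerMax = 2)
  hits <- siteRanges(scanMotif(seqs, m))
  expect_equal(bed0(hits), data.frame(chrom = "chr1", start = 0L, end = 8L))
  # spacer range scans every gap length
  seqs2 <- dna(chr1 = paste0("GGTACCC", strrep("T", 6), "GGTAACCC",
                             strrep("T", 6)))
  m2 <- motifModel("dy2", "dyad", leftWord = "GGT", rightWord = "CCC",
                   spacerMin = 1, spacerMax = 2)
  expect_equal(length(scanMotif(seqs2, m2)), 2L)
})

test_that("scanning is strand-symmetric under genome reverse complement", {
  set.seed(17)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  seqs <- dna(chr1 = s)
  rcseqs <- dna(chr1 = as.character(reverseComplement(DNAString(s))))
  m <- motifModel("m", "oligo", "RCGTCAY")
  fwd <- siteRanges(scanMotif(seqs, m))
  rev_ <- siteRanges(scanMotif(rcseqs, m))
  expect_equal(length(fwd), length(rev_))
  # mirrored coordinates: start0' = L - end0
  expect_setequal(3000 - end(rev_), start(fwd) - 1L)
  expect_equal(sort(table(as.character(strand(fwd)))),
               sort(table(as.character(strand(rev_)))))
})

test_that("palindromic consensus yields the double hit on both strands", {
  seqs <- dna(chr1 = paste0(strrep("A", 6), "CATATG", strrep("A", 6)))
  m <- motifModel("pal", "oligo", "CATATG")
  hits <- siteRanges(scanMotif(seqs, m))
  expect_equal(length(hits), 2L)
  expect_setequal(as.character(strand(hits)), c("+", "-"))
  expect_equal(unique(start(hits)), 7L)
})

test_that("enrichment fold is the midpoint-assigned density ratio", {
  g <- tinyGenome(c(chr1 = 10000L))
  # 20 sites in a 500 bp target, 100 sites over the 10 kb space -> fold 4
  sitePos <- c(seq(100, 575, by = 25), seq(1000, 8900, by = 100))
  sites <- new("MotifSiteSet",
               sites = {
                 x <- gr0("chr1", sitePos, sitePos + 6, genome = g)
                 mcols(x)$matchSeq <- rep("ACGTCA", length(x)); x
               },
               motif = motifModel("m", "oligo", "ACGTCA"))
  target <- gr0("chr1", 100, 600, genome = g)
  space <- gr0("chr1", 0, 10000, genome = g)
  res <- enrichmentFold(sites, target, space)
  expect_equal(res$nTarget, 20L); expect_equal(res$nSpace, 100L)
  expect_equal(res$fold, (20 / 500) / (100 / 10000))
  expect_equal(enrichmentFold(sites, space, space)$fold, 1.0)
  away <- gr0("chr1", 9500, 9600, genome = g)
  expect_equal(enrichmentFold(sites, away, space)$fold, 0.0)
  half <- gr0("chr1", 0, 5000, genome = g)
  expect_error(enrichmentFold(sites, gr0("chr1", 4900, 5100, genome = g),
                              half), "contained")
})

test_that("promoter space is upstream, strand-oriented and CDS-truncated", {
  g <- tinyGenome(c(chr1 = 30000L))
  gmP <- makeGenes("chr1", 10000, 12000, "+", "gA", genome = g)
  expect_equal(bed0(promoterSpace(gmP, 3000)),
               data.frame(chrom = "chr1", start = 7000L, end = 10000L))
  gmM <- makeGenes("chr1", 10000, 12000, "-", "gA", genome = g)
  expect_equal(bed0(promoterSpace(gmM, 3000)),
               data.frame(chrom = "chr1", start = 12000L, end = 15000L))
  # neighbour CDS at [8500, 9000) truncates the window to [9000, 10000)
  gm2 <- makeGenes("chr1", c(10000, 5000), c(12000, 9000), c("+", "+"),
                   c("gA", "gB"), genome = g,
                   cdsStart0 = c(10200, 8500), cdsEnd0 = c(11800, 9000))
  ps <- promoterSpace(gm2, 3000)
  expect_true(any(bed0(ps)$start == 9000 & bed0(ps)$end == 10000))
  # clipped at chromosome bounds
  gm3 <- makeGenes("chr1", 1000, 2000, "+", "gC", genome = g)
  expect_equal(bed0(promoterSpace(gm3, 3000)),
               data.frame(chrom = "chr1", start = 0L, end = 1000L))
})

test_that("TSS distances are signed in gene orientation and split by repeats", {
  g <- tinyGenome(c(chr1 = 50000L))
  gm <- makeGenes("chr1", 10000, 12000, "+", "gA", genome = g)
  mk <- function(pos0) {
    x <- gr0("chr1", pos0, pos0 + 1, genome = g)
    mcols(x)$matchSeq <- rep("A", length(x))
    new("MotifSiteSet", sites = x, motif = motifModel("m", "oligo", "ACGT"))
  }
  res <- tssDistanceSummary(mk(c(9950, 10010, 9800)), gm)
  expect_equal(res$distance, c(-50, 10, -200))
  expect_equal(res$medianNR, -50)
  expect_true(is.na(res$medianIR))
  expect_equal(res$pctInRepeats, 0)
  # site exactly at the TSS
  expect_equal(tssDistanceSummary(mk(10000), gm)$distance, 0)
  # minus-strand gene flips the sign
  gmM <- makeGenes("chr1", 10000, 12000, "-", "gA", genome = g)
  expect_equal(tssDistanceSummary(mk(12100), gmM)$distance, -101)
  # repeats split: 2 of 10 sites inside repeats -> 20%
  sites <- mk(seq(9000, 9900, by = 100))
  reps <- gr0("chr1", 9000, 9150, genome = g)
  res2 <- tssDistanceSummary(sites, gm, reps)
  expect_equal(res2$pctInRepeats, 20)
  expect_false(is.na(res2$medianIR))
})

test_that("motif site contigs merge across strands and models", {
  g <- tinyGenome(c(chr1 = 1000L))
  mk <- function(start0, end0, strand) {
    x <- gr0("chr1", start0, end0, strand, genome = g)
    mcols(x)$matchSeq <- rep("ACGT", length(x))
    new("MotifSiteSet", sites = x, motif = motifModel("m", "oligo", "ACGT"))
  }
  res <- mergeMotifSites(list(mk(10, 16, "+"), mk(13, 19, "-")))
  expect_equal(bed0(res$contigs),
               data.frame(chrom = "chr1", start = 10L, end = 19L))
  expect_equal(res$meanWidth, 9)
  # same interval on both strands collapses to one contig
  res2 <- mergeMotifSites(list(mk(50, 60, "+"), mk(50, 60, "-")))
  expect_length(res2$contigs, 1)
  # mean width is the arithmetic mean of contig widths
  res3 <- mergeMotifSites(list(mk(c(100, 200), c(109, 223), "+")))
  expect_equal(res3$meanWidth, 16)
  # contigs cover every site base
  expect_equal(overlapBp(res$contigs, mergeIntervals(
    siteRanges(mk(10, 16, "+")))), 6)
})

test_that("catalog pages are consistent with the scan and flag empty splits", {
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE,
                    prob = c(.3, .2, .2, .3)), collapse = "")
  seqs <- dna(chr1 = s)
  g <- genomeOf(seqs)
  gm <- makeGenes("chr1", 8000, 10000, "+", "gA", genome = g)
  m <- motifModel("om9", "oligo", "ACGTAC")
  sites <- scanMotif(seqs, m)
  track <- makeTrack(list(chr1 = rep(2, 2000)))
  cat1 <- buildCatalog(list(m), list(sites), gm, GRanges(seqinfo = g),
                       track, seqs)
  page <- cat1$om9
  expect_equal(page$nSites, length(sites))
  expect_true(page$ir$empty)           # no repeats annotated
  expect_false(page$nr$empty)
  expect_equal(page$pctInRepeats, 0)
  # uniform track -> flat local-coverage panel
  lc <- page$all$localCoverage
  expect_true(all(abs(lc[!is.na(lc)] - 2) < 1e-12))
  f <- withr::local_tempfile(fileext = ".txt")
  writeCatalog(cat1, f)
  expect_true(any(grepl("Motif om9", readLines(f))))
})
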