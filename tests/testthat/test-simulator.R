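# Chromatin template construction, digestion and truth-based evaluation.

test_that("templates are deterministic and carry their planted truth", {
  p <- smallTemplateParams()
  a <- buildTemplate(p, seed = 4)
  b <- buildTemplate(p, seed = 4)
  expect_identical(as.character(a@sequences), as.character(b@sequences))
  expect_identical(bed0(a@tfSites), bed0(b@tfSites))
  expect_identical(a@expression, b@expression)
  expect_equal(length(a@tfSites), 12L)
  # every truth site's centre carries an exact consensus match
  m <- p$motifs[[1]]
  hits <- siteRanges(scanMotif(a@sequences, m))
  centers0 <- floor((start(a@tfSites) - 1 + end(a@tfSites)) / 2)
  k <- nchar(m@consensus)
  covered <- vapply(centers0, function(c0)
    any(start(hits) - 1L <= c0 - (k - 1L) %/% 2L &
        end(hits) >= c0 + k %/% 2L &
        as.character(seqnames(hits)) == "chr1"), logical(1))
  expect_true(all(covered))
  # occupancy is monotone in host-gene expression for promoter sites
  prom <- a@tfSites[mcols(a@tfSites)$class == "promoter"]
  tss <- tssSites(a@geneModels)
  host <- names(tss)[nearest(prom, tss, ignore.strand = TRUE)]
  expect_gt(cor(a@expression[host], mcols(prom)$occupancy,
                method = "spearman"), 0.99)
})

test_that("digestion is seed-deterministic and respects the size selection", {
  tpl <- buildTemplate(smallTemplateParams(), seed = 4)
  dp <- smallDigestParams()
  f1 <- simulateDigest(tpl, dp, seed = 9)
  f2 <- simulateDigest(tpl, dp, seed = 9)
  expect_identical(bed0(fragmentRanges(f1)), bed0(fragmentRanges(f2)))
  w <- width(fragmentRanges(f1))
  expect_true(all(w >= dp$sizeRange[1] & w <= dp$sizeRange[2]))
  expect_true(all(start(fragmentRanges(f1)) >= 1 &
                  end(fragmentRanges(f1)) <= 60000))
  # depth subsampling caps the pool
  f3 <- simulateDigest(tpl, smallDigestParams(depth = 500), seed = 9)
  expect_equal(totalCount(f3), 500L)
})

test_that("fully occupied sites exclude fragment boundaries", {
  p <- smallTemplateParams(piRange = c(1, 1))
  tpl <- buildTemplate(p, seed = 6)
  dp <- smallDigestParams(protectionCompleteness = 1)
  fs <- simulateDigest(tpl, dp, seed = 10)
  gr <- fragmentRanges(fs)
  bounds0 <- c(start(gr) - 1L, end(gr))
  s0 <- start(tpl@tfSites) - 1L; e0 <- end(tpl@tfSites)
  inside <- vapply(seq_along(s0), function(i)
    sum(bounds0 > s0[i] & bounds0 < e0[i]), numeric(1))
  expect_true(all(inside == 0))
})

test_that("the naked-DNA control is unprotected and spatially uniform", {
  tpl <- buildTemplate(smallTemplateParams(), seed = 4)
  ctl <- simulateControl(tpl, smallDigestParams(), seed = 11)
  mids <- start(fragmentMidpoints(ctl)) - 1L
  # FRiP of the control in the truth sites ~ truth bp fraction of the genome
  truth <- mergeIntervals(granges(tpl@tfSites))
  fr <- frip(ctl, truth)
  expected <- sum(width(truth)) / 60000
  expect_lt(abs(fr - expected), 3 * sqrt(expected / totalCount(ctl)) +
                                 0.2 * expected)
  # two equal halves of the chromosome receive similar midpoint counts
  nLeft <- sum(mids < 30000); nRight <- sum(mids >= 30000)
  expect_lt(abs(nLeft - nRight) / sqrt(length(mids)), 4)
})

test_that("A/T cut bias raises cut density in AT-rich windows", {
  # half AT, half GC chromosome isolates the compositional effect; a wide
  # size range keeps essentially every fragment so boundaries trace cuts
  tpl <- new("ChromatinTemplate",
             sequences = DNAStringSet(c(chr1 = paste0(
               strrep("AT", 15000), strrep("GC", 15000)))),
             geneModels = geneModelSet(GRanges()),
             expression = numeric(0), nucleosomes = GRanges(),
             tfSites = GRanges(), repeats = GRanges())
  ctl <- simulateControl(tpl, digestParams(nMolecules = 5L,
                                           sizeRange = c(2L, 10000L),
                                           controlAtBias = 3), seed = 12)
  bounds0 <- start(fragmentRanges(ctl)) - 1L
  nAT <- sum(bounds0 < 30000 & bounds0 > 0)
  nGC <- sum(bounds0 >= 30000)
  expect_gt(nAT / nGC, 2)       # ~3x cut rate on the AT half
  # unbiased control splits evenly
  ctl0 <- simulateControl(tpl, digestParams(nMolecules = 5L,
                                            sizeRange = c(2L, 10000L)),
                          seed = 13)
  b0 <- start(fragmentRanges(ctl0)) - 1L
  expect_lt(abs(sum(b0 < 30000) - sum(b0 >= 30000)) / length(b0), 0.05)
})

test_that("evaluateTruth computes recall, precision and centre error", {
  g <- tinyGenome(c(chr1 = 10000L))
  truth <- gr0("chr1", seq(100, 1000, by = 100), seq(100, 1000, by = 100) + 20,
               genome = g)
  # peaks identical to truth
  ev <- evaluateTruth(truth, truth, tol = 10)
  expect_equal(ev$recall, 1); expect_equal(ev$precision, 1)
  expect_equal(ev$medianCenterError, 0)
  # peaks shifted +50 bp with tol 10 recover nothing
  ev2 <- evaluateTruth(shift(truth, 50), truth, tol = 10)
  expect_equal(ev2$recall, 0)
  expect_equal(ev2$medianCenterError, 50)
  # 8 of 10 truth sites hit, 8 of 12 peaks matched
  peaks <- c(shift(truth[1:8], 2),
             gr0("chr1", c(5000, 6000, 7000, 8000),
                 c(5030, 6030, 7030, 8030), genome = g))
  ev3 <- evaluateTruth(peaks, truth, tol = 10)
  expect_equal(ev3$recall, 0.8)
  expect_equal(ev3$precision, 8 / 12)
  expect_error(evaluateTruth(truth, GRanges(), tol = 10), "empty truth")
})

test_that("templates round trip through the on-disk formats", {
  tpl <- buildTemplate(smallTemplateParams(), seed = 4)
  dir <- withr::local_tempdir()
  files <- writeTemplate(tpl, dir)
  expect_true(all(file.exists(files)))
  seqs <- readGenomeFasta(files[["fasta"]])
  expect_identical(as.character(seqs), as.character(tpl@sequences))
  g <- genomeOf(seqs)
  gm <- readGeneModels(files[["gff3"]], g)
  expect_setequal(names(geneBodies(gm)), names(geneBodies(tpl@geneModels)))
  truth <- readBed(files[["tfSites"]], g)
  expect_equal(length(truth), length(tpl@tfSites))
  expect_equal(unname(mcols(truth)$score),
               unname(mcols(tpl@tfSites)$occupancy), tolerance = 1e-3)
  ex <- read.table(files[["expression"]], header = TRUE, sep = "\t")
  expect_equal(setNames(ex$expression, ex$gene_id), tpl@expression)
})
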