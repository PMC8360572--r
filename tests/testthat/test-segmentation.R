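# BC segmentation: support statistics, peak calling against the brute-force
# reference, merging and genomic-fraction calibration.

test_that("scale statistics use non-zero support with sample SD and plain MAD", {
  st <- scaleStats(makeTrack(list(chr1 = c(2, 4, 6))))
  expect_equal(st@mean, 4); expect_equal(st@sd, 2); expect_equal(st@mad, 2)
  # zeros excluded from support
  st2 <- scaleStats(makeTrack(list(chr1 = c(0, 0, 2, 4, 6, 0))))
  expect_equal(c(st2@mean, st2@sd, st2@mad), c(4, 2, 2))
  # degenerate constant support: sd 0 -> downstream segmentation errors
  st3 <- scaleStats(makeTrack(list(chr1 = c(5, 5, 5, 0))))
  expect_equal(st3@sd, 0)
  expect_error(callSegments(makeTrack(list(chr1 = c(5, 5, 5, 0))), st3,
                            segmentationParams(bc = 1)), "zero")
  expect_error(scaleStats(makeTrack(list(chr1 = c(0, 0, 1)))), "support")
  # support can come from a pooled source track
  tr <- makeTrack(list(chr1 = c(9, 1, 3, 7)))
  pool <- makeTrack(list(chr1 = c(1, 0, 2, 3)))
  st4 <- scaleStats(tr, supportSource = pool)
  expect_equal(st4@mean, mean(c(9, 3, 7)))
})

test_that("callSegments reproduces the worked single-peak and tie-break cases", {
  st <- makeStats(mean = 0, sd = 1)
  # z-bins [0,0,3,3,0,0], bin 10 bp, bc 2 -> one [20,40) segment, t = 3*sqrt(2)
  tr <- makeTrack(list(chr1 = c(0, 0, 3, 3, 0, 0)))
  seg <- callSegments(tr, st, segmentationParams(bc = 2))
  p <- peakRanges(seg)
  expect_equal(bed0(p), data.frame(chrom = "chr1", start = 20L, end = 40L))
  expect_equal(mcols(p)$meanHeight, 3)
  expect_equal(mcols(p)$tStat, 3 * sqrt(2))
  expect_equal(mcols(p)$pValue, pnorm(3 * sqrt(2), lower.tail = FALSE))
  # all-zero track -> empty set
  seg0 <- callSegments(makeTrack(list(chr1 = rep(0, 10))), st,
                       segmentationParams(bc = 2))
  expect_length(peakRanges(seg0), 0)
  expect_equal(genomeFraction(seg0), 0)
  # two equal disjoint blocks: both reported, earlier start first
  tr2 <- makeTrack(list(chr1 = c(0, 3, 3, 0, 0, 0, 3, 3, 0, 0)))
  seg2 <- callSegments(tr2, st, segmentationParams(bc = 2))
  expect_equal(bed0(peakRanges(seg2))$start, c(10L, 60L))
  expect_equal(mcols(peakRanges(seg2))$tStat, rep(3 * sqrt(2), 2))
})

test_that("callSegments matches the exhaustive brute-force reference", {
  set.seed(42)
  for (i in 1:40) {
    nBins <- sample(40:500, 1)
    step <- sample(c(5L, 10L), 1)
    tr <- randomTrack(nBins, step = step)
    st <- scaleStats(tr)
    if (st@sd == 0) next
    bc <- sample(c(0.5, 1, 2, 3), 1)
    params <- segmentationParams(bc = bc, mergeGap = 1L)
    got <- peakRanges(callSegments(tr, st, params))
    want <- bruteForceSegments(trackValues(tr, "chrT"), st@mean, st@sd, bc,
                               20L, 120L, step = step, mergeGap = 1L)
    expect_equal(start(got) - 1L, want$start0)
    expect_equal(end(got), want$end0)
    expect_equal(mcols(got)$meanHeight, want$meanHeight, tolerance = 1e-9)
    expect_equal(mcols(got)$tStat, want$tStat, tolerance = 1e-9)
  }
})

test_that("genome fraction is non-increasing in bc and peaks respect the cutoff", {
  set.seed(8)
  tr <- randomTrack(400)
  st <- scaleStats(tr)
  fr <- vapply(c(0.5, 1, 2, 3, 5), function(bc)
    genomeFraction(callSegments(tr, st, segmentationParams(bc = bc))),
    numeric(1))
  expect_true(all(diff(fr) <= 0))
  # pre-merge heights: with far-apart peaks merging is a no-op, so every
  # reported segment's meanHeight is >= mean + bc * sd
  v <- rep(0, 200); v[c(50, 51, 120, 121)] <- c(8, 9, 12, 14); v[1:10] <- 1
  tr2 <- makeTrack(list(chr1 = v))
  st2 <- scaleStats(tr2)
  seg <- callSegments(tr2, st2, segmentationParams(bc = 1))
  expect_true(all(mcols(peakRanges(seg))$meanHeight >=
                  st2@mean + 1 * st2@sd - 1e-9))
  # merged neighbours are separated by more than mergeGap
  set.seed(12)
  for (i in 1:10) {
    tr3 <- randomTrack(300)
    st3 <- scaleStats(tr3)
    if (st3@sd == 0) next
    p <- peakRanges(callSegments(tr3, st3, segmentationParams(bc = 1)))
    if (length(p) > 1)
      expect_true(all(start(p)[-1] - end(p)[-length(p)] - 1L > 1L))
  }
})

test_that("calibration selects the most stringent cutoff inside the target band", {
  # engineered track: three block strengths so successive cutoffs capture
  # strictly decreasing genome fractions
  v <- rep(0, 4000)
  v[seq(15, 3995, by = 40)] <- 1                       # background support
  weak <- seq(100, 460, by = 40)                        # 10 blocks of 1 bin
  med <- seq(1000, 1760, by = 40)
  strong <- seq(3000, 3120, by = 40)
  v[weak] <- 30; v[weak + 1] <- 30
  v[med] <- 60; v[med + 1] <- 60
  v[strong] <- 120; v[strong + 1] <- 120
  tr <- makeTrack(list(chr1 = v))
  st <- scaleStats(tr)
  zOf <- function(h) (h - st@mean) / st@sd
  grid <- c(zOf(30) - 0.5, zOf(60) - 0.5, zOf(120) - 0.5)
  frAll <- calibrateBc(tr, st, bcGrid = grid,
                       targetFraction = c(0, 1))$fractions
  expect_true(all(diff(frAll) < 0))
  # only the middle cutoff's fraction falls in the band -> it is selected
  band <- sort(c(mean(frAll[2:3]), frAll[2] + 1e-6))
  sel <- calibrateBc(tr, st, bcGrid = grid, targetFraction = band)
  expect_equal(sel$bc, grid[2])
  # two cutoffs in band -> the larger (more stringent) wins
  band2 <- c(frAll[3] - 1e-6, frAll[2] + 1e-6)
  sel2 <- calibrateBc(tr, st, bcGrid = grid, targetFraction = band2)
  expect_equal(sel2$bc, grid[3])
  # none in band -> nearest, with a warning
  expect_warning(
    sel3 <- calibrateBc(tr, st, bcGrid = grid[1:2],
                        targetFraction = c(frAll[3] / 4, frAll[3] / 2)),
    "nearest")
  expect_equal(sel3$bc, grid[2])
})

test_that("six-column segment tables round trip", {
  st <- makeStats()
  tr <- makeTrack(list(chr1 = c(0, 0, 3, 3, 0, 0), chr2 = c(4, 4, 0, 0, 0, 0)))
  seg <- callSegments(tr, st, segmentationParams(bc = 2))
  f <- withr::local_tempfile(fileext = ".txt")
  writeSegmentTable(seg, f)
  tab <- read.table(f, sep = "\t")
  expect_equal(ncol(tab), 6L)
  back <- readSegmentTable(f, trackGenome(tr))
  expect_identical(bed0(peakRanges(back)), bed0(peakRanges(seg)))
  expect_equal(mcols(peakRanges(back))$meanHeight,
               mcols(peakRanges(seg))$meanHeight)
  expect_equal(mcols(peakRanges(back))$tStat, mcols(peakRanges(seg))$tStat)
  expect_equal(mcols(peakRanges(back))$pValue, mcols(peakRanges(seg))$pValue)
})
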