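# Biological-cutoff (BC) segmentation of signal tracks into peaks, merging,
# and genomic-fraction calibration.
#
# Contract: standardize each grid record by the track's support statistics,
# enumerate candidate segments of minWindow..maxWindow bp on the grid, keep
# candidates whose mean standardized value reaches the BC, score them by
# t = mean(z) * sqrt(n records), select non-overlapping candidates greedily
# by descending t (ties: smaller start, then smaller width), then merge
# book-ended/1 bp-gap survivors into final peaks.

#' Segmentation parameters
#'
#' @param bc biological cutoff: a significant segment's mean height must
#'   exceed the track mean by at least `bc` scale units (> 0).
#' @param minWindow,maxWindow candidate window lengths in bp (defaults 20 and
#'   120).
#' @param mergeGap merge surviving segments separated by at most this many bp
#'   (default 1: book-ended or 1 bp apart).
#' @param scale `"sd"` (default) or `"mad"` (robust alternative).
#' @return a [SegmentationParams].
#' @export
segmentationParams <- function(bc, minWindow = 20L, maxWindow = 120L,
                               mergeGap = 1L, scale = c("sd", "mad")) {
  new("SegmentationParams", bc = as.numeric(bc),
      minWindow = as.integer(minWindow), maxWindow = as.integer(maxWindow),
      mergeGap = as.integer(mergeGap), scale = match.arg(scale))
}

#' Support statistics of a track
#'
#' Sample mean, SD (n-1 denominator) and plain median absolute deviation of
#' the track values over its support: the bins where the support source (by
#' default the track itself; for pooled peak calling, the combined pool) is
#' non-zero. Excluding global zero regions avoids the distortion caused by
#' genome-scale sparsity.
#'
#' @param track a [CoverageTrack].
#' @param supportSource optional [CoverageTrack] defining the support (same
#'   geometry as `track`).
#' @return a [ScaleStats].
#' @export
scaleStats <- function(track, supportSource = NULL) {
  src <- if (is.null(supportSource)) track else supportSource
  if (!identical(lengths(src@values), lengths(track@values)))
    stop("support source geometry mismatch")
  support <- lapply(as.list(src@values), function(v) v != 0)
  vals <- unlist(mapply(function(v, s) v[s], as.list(track@values), support,
                        SIMPLIFY = FALSE), use.names = FALSE)
  if (length(vals) < 2L) stop("need >= 2 support bins to compute statistics")
  new("ScaleStats", mean = mean(vals), sd = sd(vals),
      mad = mad(vals, constant = 1), support = SimpleList(support))
}

# Candidate enumeration + greedy selection on one chromosome's record vector.
# Returns a data.frame of selected segments in record indices.
.segmentChrom <- function(v, mu, s, bc, nbMin, nbMax) {
  n <- length(v)
  if (n == 0L) return(NULL)
  z <- (v - mu) / s
  cs <- c(0, cumsum(z))
  starts <- integer(0); nbs <- integer(0); means <- numeric(0)
  for (nb in nbMin:min(nbMax, n)) {
    m <- (cs[(nb + 1L):(n + 1L)] - cs[1:(n - nb + 1L)]) / nb
    hit <- which(m >= bc - 1e-9)   # tolerance keeps boundary cases stable
    if (length(hit)) {
      starts <- c(starts, hit)
      nbs <- c(nbs, rep.int(nb, length(hit)))
      means <- c(means, m[hit])
    }
  }
  if (length(starts) == 0L) return(NULL)
  tstat <- means * sqrt(nbs)
  # ties in t (to 9 decimals, absorbing float noise) break by smaller start,
  # then smaller width
  ord <- order(-round(tstat, 9), starts, nbs)
  occupied <- logical(n)
  keep <- logical(length(ord))
  for (k in ord) {
    i <- starts[k]; j <- i + nbs[k] - 1L
    if (!any(occupied[i:j])) {
      occupied[i:j] <- TRUE
      keep[k] <- TRUE
    }
  }
  sel <- which(keep)
  data.frame(start = starts[sel], nb = nbs[sel], meanZ = means[sel],
             tStat = tstat[sel])
}

#' Call segments (peaks) on a track
#'
#' Implements the segmentation contract described above. Reported
#' `meanHeight` is the mean raw track value over the segment (which for a
#' pre-standardized track equals the mean z); `tStat` is the mean
#' standardized value times `sqrt(records)`; `pValue` is the one-sided
#' standard-normal tail of `tStat` (an uncorrected approximation carried to
#' fill the six-column output convention - thresholding is by BC, never by
#' p). Merged segments recompute `meanHeight` as the bp-weighted mean and
#' take the maximum constituent `tStat`.
#'
#' @param track a [CoverageTrack].
#' @param stats a [ScaleStats] for the track.
#' @param params a [SegmentationParams].
#' @return a [SegmentSet].
#' @export
callSegments <- function(track, stats, params) {
  s <- if (params@scale == "sd") stats@sd else stats@mad
  if (s <= 0) stop("scale statistic is zero; segmentation undefined")
  step <- track@step
  nbMin <- max(1L, as.integer(ceiling(params@minWindow / step)))
  nbMax <- max(nbMin, as.integer(floor(params@maxWindow / step)))
  sl <- seqlengths(track@genome)
  parts <- list()
  for (ch in names(sl)) {
    seg <- .segmentChrom(track@values[[ch]], stats@mean, s, params@bc,
                         nbMin, nbMax)
    if (is.null(seg)) next
    start1 <- (seg$start - 1L) * step + 1L
    end1 <- pmin((seg$start + seg$nb - 1L) * step, sl[[ch]])
    gr <- GRanges(ch, IRanges(start1, end1), seqinfo = track@genome)
    mcols(gr)$meanHeight <- stats@mean + seg$meanZ * s
    mcols(gr)$tStat <- seg$tStat
    parts[[ch]] <- gr
  }
  peaks <- if (length(parts)) sort(do.call(c, unname(parts)))
           else GRanges(seqinfo = track@genome)
  peaks <- .mergeSegments(peaks, params@mergeGap)
  if (length(peaks)) mcols(peaks)$pValue <-
      pnorm(mcols(peaks)$tStat, lower.tail = FALSE)
  else {
    mcols(peaks)$meanHeight <- numeric(0)
    mcols(peaks)$tStat <- numeric(0)
    mcols(peaks)$pValue <- numeric(0)
  }
  gf <- sum(as.numeric(width(peaks))) / sum(as.numeric(sl))
  mw <- if (length(peaks)) mean(width(peaks)) else NA_real_
  new("SegmentSet", peaks = peaks, params = params, genomeFraction = gf,
      meanWidth = mw)
}

# Merge segments separated by <= gap bp; bp-weighted meanHeight, max tStat.
.mergeSegments <- function(peaks, gap) {
  if (length(peaks) < 2L) return(peaks)
  merged <- reduce(peaks, min.gapwidth = gap + 1L, ignore.strand = TRUE)
  hits <- findOverlaps(peaks, merged)
  grp <- S4Vectors::subjectHits(hits)
  w <- as.numeric(width(peaks))
  mh <- as.numeric(tapply(mcols(peaks)$meanHeight * w, grp, sum) /
                   tapply(w, grp, sum))
  ts <- as.numeric(tapply(mcols(peaks)$tStat, grp, max))
  mcols(merged)$meanHeight <- mh
  mcols(merged)$tStat <- ts
  merged
}

#' Calibrate the biological cutoff by genomic-fraction equivalency
#'
#' Runs [callSegments()] at each cutoff in `bcGrid` and returns the largest
#' (most stringent) cutoff whose called peaks capture a genome fraction
#' inside `targetFraction`. If none qualifies, the cutoff whose fraction is
#' nearest to the target interval is returned with a warning. Defaults are the
#' conventional equivalency bands for maize-scale data: 0.5-0.7% of the
#' genome for coverage tracks, 0.1-0.2% for fragment-center (frenter)
#' tracks.
#'
#' @param track a [CoverageTrack].
#' @param stats a [ScaleStats] for the track.
#' @param bcGrid increasing vector of candidate cutoffs (default
#'   `c(1, 2, 3, 4, 5, 7, 9)`).
#' @param targetFraction `c(low, high)` genome-fraction band; default depends
#'   on the track kind.
#' @param params template [SegmentationParams]; its `bc` is replaced by each
#'   grid value.
#' @return a list with elements `bc` (selected cutoff), `segments` (the
#'   [SegmentSet] at that cutoff) and `fractions` (named genome fractions for
#'   the whole grid).
#' @export
calibrateBc <- function(track, stats, bcGrid = c(1, 2, 3, 4, 5, 7, 9),
                        targetFraction = NULL,
                        params = segmentationParams(bc = 1)) {
  if (length(bcGrid) == 0L || is.unsorted(bcGrid, strictly = TRUE))
    stop("bcGrid must be non-empty and strictly increasing")
  if (is.null(targetFraction))
    targetFraction <- if (track@kind == "frenter") c(0.001, 0.002)
                      else c(0.005, 0.007)
  runs <- lapply(bcGrid, function(bc) {
    p <- params; p@bc <- as.numeric(bc)
    callSegments(track, stats, p)
  })
  fr <- vapply(runs, genomeFraction, numeric(1))
  names(fr) <- as.character(bcGrid)
  inBand <- fr >= targetFraction[1] & fr <= targetFraction[2]
  if (any(inBand)) {
    pick <- max(which(inBand))   # largest bc = most stringent
  } else {
    dist <- pmax(targetFraction[1] - fr, fr - targetFraction[2], 0)
    pick <- which.min(dist)
    warning("no cutoff reached the target genome fraction [",
            targetFraction[1], ", ", targetFraction[2],
            "]; returning the nearest (bc = ", bcGrid[pick], ", fraction ",
            signif(fr[pick], 3), ")")
  }
  list(bc = bcGrid[pick], segments = runs[[pick]], fractions = fr)
}

#' Write the six-column segment table
#'
#' Tab-delimited, no header: chrom, SegmentStart, SegmentEnd (0-based
#' half-open), meanHeight, t-statistic, p-value.
#'
#' @param x a [SegmentSet].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSegmentTable <- function(x, file) {
  p <- peakRanges(x)
  tab <- data.frame(chrom = as.character(seqnames(p)), start = start(p) - 1L,
                    end = end(p), meanHeight = mcols(p)$meanHeight,
                    tStat = mcols(p)$tStat, pValue = mcols(p)$pValue)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a six-column segment table
#'
#' @param file path to a table written by [writeSegmentTable()].
#' @param genome optional [GenomeInfoDb::Seqinfo].
#' @param params the [SegmentationParams] to attach (metadata only).
#' @return a [SegmentSet]. `genomeFraction` is computed when a genome is
#'   supplied, otherwise `NA`.
#' @export
readSegmentTable <- function(file, genome = NULL,
                             params = segmentationParams(bc = 1)) {
  tab <- read.table(file, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "meanHeight",
                                  "tStat", "pValue"),
                    colClasses = c("character", "integer", "integer",
                                   "numeric", "numeric", "numeric"))
  gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
  if (!is.null(genome)) gr <- .applyGenome(gr, genome)
  mcols(gr)$meanHeight <- tab$meanHeight
  mcols(gr)$tStat <- tab$tStat
  mcols(gr)$pValue <- tab$pValue
  gf <- if (is.null(genome) || any(is.na(seqlengths(genome)))) NA_real_
        else sum(as.numeric(width(gr))) / sum(as.numeric(seqlengths(genome)))
  mw <- if (length(gr)) mean(width(gr)) else NA_real_
  new("SegmentSet", peaks = gr, params = params,
      genomeFraction = ifelse(is.na(gf), 0, gf), meanWidth = mw)
}
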