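# Reproducibility and enrichment quality metrics.

#' Fraction of reads in peaks (FRiP)
#'
#' Fraction of fragments whose midpoint lies within any peak interval.
#' Midpoints (not any-overlap) are counted for consistency with the
#' fragment-center footprint logic: the midpoint is the assay's signal
#' carrier.
#'
#' @param fs a [FragmentSet] (must be non-empty).
#' @param peaks a [SegmentSet] or merged `GRanges`.
#' @return FRiP in `[0, 1]`.
#' @export
frip <- function(fs, peaks) {
  if (totalCount(fs) == 0L) stop("FRiP undefined for an empty FragmentSet")
  gr <- if (is(peaks, "SegmentSet")) peakRanges(peaks) else peaks
  mids <- fragmentMidpoints(fs)
  mean(overlapsAny(mids, gr, ignore.strand = TRUE))
}

#' Pearson correlation between two tracks
#'
#' Computed over included bins; `restrict = "nonzero_union"` (the default)
#' includes bins that are non-zero in either track, because genome-scale
#' sparsity otherwise inflates the correlation.
#'
#' @param a,b [CoverageTrack] objects with identical geometry.
#' @param restrict `"nonzero_union"` or `"all"`.
#' @return Pearson's r.
#' @export
trackCorrelation <- function(a, b, restrict = c("nonzero_union", "all")) {
  restrict <- match.arg(restrict)
  if (!identical(lengths(a@values), lengths(b@values)) ||
      a@step != b@step)
    stop("track geometry mismatch")
  x <- unlist(as.list(a@values), use.names = FALSE)
  y <- unlist(as.list(b@values), use.names = FALSE)
  if (restrict == "nonzero_union") {
    keep <- x != 0 | y != 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined (constant or near-empty vectors)")
  cor(x, y)
}

#' Base sharing between two peak sets
#'
#' Shared base pairs within overlapping peaks, and the shared fraction of
#' each set's total peak bases. `sharedBp` is symmetric; the fractions are
#' not.
#'
#' @param a,b [SegmentSet] objects or merged `GRanges`.
#' @return a list with `sharedBp`, `fracOfA`, `fracOfB`.
#' @export
baseSharing <- function(a, b) {
  ga <- if (is(a, "SegmentSet")) peakRanges(a) else a
  gb <- if (is(b, "SegmentSet")) peakRanges(b) else b
  bpA <- sum(as.numeric(width(ga)))
  bpB <- sum(as.numeric(width(gb)))
  if (bpA == 0 || bpB == 0) stop("base sharing undefined for an empty set")
  shared <- overlapBp(ga, gb)
  list(sharedBp = shared, fracOfA = shared / bpA, fracOfB = shared / bpB)
}

#' Reciprocal any-overlap peak intersection counts
#'
#' Number of `a`-peaks overlapping at least 1 bp of any `b`-peak, and vice
#' versa (the counts are asymmetric in general: one `a`-peak spanning two
#' `b`-peaks counts once on the `a` side and twice on the `b` side).
#'
#' @param a,b [SegmentSet] objects or merged `GRanges`.
#' @return a list with `countAHit`, `countBHit`.
#' @export
peakIntersection <- function(a, b) {
  ga <- if (is(a, "SegmentSet")) peakRanges(a) else a
  gb <- if (is(b, "SegmentSet")) peakRanges(b) else b
  list(countAHit = sum(overlapsAny(ga, gb, ignore.strand = TRUE)),
       countBHit = sum(overlapsAny(gb, ga, ignore.strand = TRUE)))
}

#' Assemble a QC report
#'
#' Convenience wrapper computing the reproducibility panel for a pair of
#' replicate libraries: FRiP of each replicate in the pooled peaks, track
#' correlation between replicates (and against an optional control), base
#' sharing and reciprocal intersections between per-replicate peak sets.
#'
#' @param fsA,fsB replicate [FragmentSet]s.
#' @param trackA,trackB their [CoverageTrack]s (identical geometry).
#' @param peaksA,peaksB their [SegmentSet]s.
#' @param controlTrack optional control [CoverageTrack].
#' @return a one-row `data.frame`.
#' @export
qcReport <- function(fsA, fsB, trackA, trackB, peaksA, peaksB,
                     controlTrack = NULL) {
  sharing <- baseSharing(peaksA, peaksB)
  hits <- peakIntersection(peaksA, peaksB)
  data.frame(
    fripA = frip(fsA, peaksA),
    fripB = frip(fsB, peaksB),
    pearsonR = trackCorrelation(trackA, trackB),
    controlR = if (is.null(controlTrack)) NA_real_
               else trackCorrelation(trackA, controlTrack),
    sharedBp = sharing$sharedBp,
    fracSharedA = sharing$fracOfA,
    fracSharedB = sharing$fracOfB,
    peaksAHit = hits$countAHit,
    peaksBHit = hits$countBHit)
}
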