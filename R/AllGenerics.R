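#' @rdname FragmentSet-class
#' @param x,object a package object.
#' @export
setGeneric("fragmentRanges", function(x) standardGeneric("fragmentRanges"))

#' @rdname FragmentSet-class
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname FragmentSet-class
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackGenome", function(x) standardGeneric("trackGenome"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackStep", function(x) standardGeneric("trackStep"))

#' @rdname CoverageTrack-class
#' @param chrom optional chromosome name to restrict to.
#' @export
setGeneric("trackValues", function(x, chrom = NULL)
  standardGeneric("trackValues"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackNormalization", function(x)
  standardGeneric("trackNormalization"))

#' @rdname SegmentSet-class
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname SegmentSet-class
#' @export
setGeneric("genomeFraction", function(x) standardGeneric("genomeFraction"))

#' @rdname SegmentSet-class
#' @export
setGeneric("meanWidth", function(x) standardGeneric("meanWidth"))

#' @rdname SegmentSet-class
#' @export
setGeneric("segmentParams", function(x) standardGeneric("segmentParams"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneBodies", function(x) standardGeneric("geneBodies"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("cdsParts", function(x) standardGeneric("cdsParts"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("tssSites", function(x) standardGeneric("tssSites"))

#' @rdname MotifSiteSet-class
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname MotifSiteSet-class
#' @export
setGeneric("motifOf", function(x) standardGeneric("motifOf"))

#' Deduplicate fragments
#'
#' Retains at most one fragment per (chrom, start, end) key. Strand is not
#' part of the key: paired-end duplicates of an unstranded duplex share both
#' ends regardless of read orientation. The result is order-independent
#' (output is coordinate-sorted) and the operation is idempotent.
#'
#' @param x a [FragmentSet].
#' @return a [FragmentSet] with duplicates removed.
#' @export
setGeneric("deduplicate", function(x) standardGeneric("deduplicate"))

#' Filter fragments by maximum length
#'
#' Retains fragments of length `<= maxLen` (inclusive, matching the "<= 80 bp"
#' small-fragment class). `maxLen = 0` is the "all sizes" sentinel and returns
#' the input unchanged. Relative order is preserved.
#'
#' @param x a [FragmentSet].
#' @param maxLen maximum fragment length in bp; 0 keeps all sizes.
#' @return a filtered [FragmentSet].
#' @export
setGeneric("filterBySize", function(x, maxLen = 80L)
  standardGeneric("filterBySize"))

#' Fragment geometric centers
#'
#' The midpoint of a fragment spanning 0-based half-open `[start, end)` is
#' `floor((start + end) / 2)`; even-length fragments take the left-of-center
#' base so window arithmetic stays exact. Returned as width-1 ranges.
#'
#' @param x a [FragmentSet] or `GRanges`.
#' @return a `GRanges` of width-1 midpoint positions.
#' @export
setGeneric("fragmentMidpoints", function(x)
  standardGeneric("fragmentMidpoints"))
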