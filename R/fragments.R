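# Fragment ingestion, deduplication, size-class filtering and midpoint
# extraction.

#' Construct a FragmentSet
#'
#' @param fragments a `GRanges` of aligned fragment intervals (strand is
#'   ignored; fragments are unstranded duplexes).
#' @param libraryId library label.
#' @return a [FragmentSet].
#' @export
fragmentSet <- function(fragments, libraryId = "library") {
  fragments <- granges(fragments)
  strand(fragments) <- "*"
  new("FragmentSet", fragments = fragments, libraryId = libraryId)
}

#' Read fragments from a BED file
#'
#' One record per sequenced fragment (BED3+).
#'
#' @param file path to the fragment BED.
#' @param genome optional [GenomeInfoDb::Seqinfo] for bounds checking.
#' @param libraryId library label; defaults to the file name.
#' @return a [FragmentSet].
#' @export
readFragments <- function(file, genome = NULL, libraryId = NULL) {
  if (is.null(libraryId))
    libraryId <- sub("\\.bed(\\.gz)?$", "", basename(file))
  fragmentSet(readBed(file, genome), libraryId)
}

#' Write fragments as BED3
#'
#' @param x a [FragmentSet].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeFragments <- function(x, file) {
  writeBed(granges(fragmentRanges(x)), file)
}

#' Pool several fragment libraries
#'
#' @param ... [FragmentSet] objects (or a single list of them).
#' @param libraryId label for the pool.
#' @return a [FragmentSet] with the concatenated fragments.
#' @export
poolFragments <- function(..., libraryId = "pool") {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]])) sets <- sets[[1L]]
  gr <- do.call(c, lapply(sets, fragmentRanges))
  fragmentSet(gr, libraryId)
}

#' @rdname deduplicate
setMethod("deduplicate", "FragmentSet", function(x) {
  gr <- sort(unique(granges(fragmentRanges(x))))
  initialize(x, fragments = gr)
})

#' @rdname filterBySize
setMethod("filterBySize", "FragmentSet", function(x, maxLen = 80L) {
  if (maxLen < 0L) stop("maxLen must be >= 0")
  if (maxLen == 0L) return(x)   # sentinel: all sizes
  gr <- fragmentRanges(x)
  initialize(x, fragments = gr[width(gr) <= maxLen])
})

#' @rdname fragmentMidpoints
setMethod("fragmentMidpoints", "GRanges", function(x) {
  # 0-based midpoint floor((start0 + end0)/2); +1 back to 1-based coordinates
  mid0 <- (start(x) - 1L + end(x)) %/% 2L
  out <- GRanges(seqnames(x), IRanges(mid0 + 1L, width = 1L),
                 seqinfo = seqinfo(x))
  out
})

#' @rdname fragmentMidpoints
setMethod("fragmentMidpoints", "FragmentSet", function(x) {
  fragmentMidpoints(fragmentRanges(x))
})
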