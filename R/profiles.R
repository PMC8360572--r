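# Normalized coverage tracks and fragment-center ("frenter") footprint
# tracks; control subtraction.

.newTrack <- function(genome, binWidth, step, values, normalization, kind,
                      nFragments = NA_real_) {
  new("CoverageTrack", genome = genome, binWidth = as.integer(binWidth),
      step = as.integer(step), values = SimpleList(values),
      normalization = normalization, kind = kind,
      nFragments = as.numeric(nFragments))
}

#' Binned fragment coverage track
#'
#' Per-bin value is the mean per-base fragment depth within the bin (so the
#' value is invariant to bin width at uniform depth and matches bedGraph
#' display semantics). An empty fragment set yields an all-zero track with a
#' warning.
#'
#' @param fs a [FragmentSet].
#' @param genome a [GenomeInfoDb::Seqinfo]; defaults to the fragments'
#'   seqinfo (which must then carry lengths).
#' @param binWidth bin width in bp (default 10).
#' @return a raw [CoverageTrack] of kind `"coverage"`.
#' @export
coverageTrack <- function(fs, genome = NULL, binWidth = 10L) {
  gr <- fragmentRanges(fs)
  if (is.null(genome)) {
    genome <- seqinfo(gr)
    if (any(is.na(seqlengths(genome))))
      stop("genome lengths unknown; supply a genome table")
  }
  if (length(gr) == 0L) warning("empty FragmentSet: all-zero coverage track")
  gr <- .applyGenome(gr, genome)
  cov <- coverage(gr)
  sl <- seqlengths(genome)
  vals <- lapply(names(sl), function(ch) {
    n <- ceiling(sl[[ch]] / binWidth)
    starts <- seq.int(1L, by = binWidth, length.out = n)
    ends <- pmin(starts + binWidth - 1L, sl[[ch]])
    as.numeric(viewMeans(Views(cov[[ch]], start = starts, end = ends)))
  })
  names(vals) <- names(sl)
  .newTrack(genome, binWidth, binWidth, vals, "raw", "coverage",
            nFragments = length(gr))
}

#' Fragment-center ("frenter") footprint track
#'
#' Counts fragment midpoints in sliding windows of `window` bp advanced by
#' `step` bp, anchored at multiples of `step` (0-based). Each step-grid record
#' carries the count of the full window starting there; windows overlap,
#' records do not, so the track is bedGraph-legal. Chromosome-edge windows
#' are truncated without rescaling.
#'
#' @param fs a [FragmentSet] (deduplicate/size-filter upstream as desired).
#' @param genome a [GenomeInfoDb::Seqinfo]; defaults to the fragments'
#'   seqinfo.
#' @param window window width in bp (odd, default 21).
#' @param step grid step in bp (default 5; must not exceed `window`).
#' @return a raw [CoverageTrack] of kind `"frenter"`.
#' @export
frenterTrack <- function(fs, genome = NULL, window = 21L, step = 5L) {
  if (window %% 2L == 0L || window < step)
    stop("window must be odd and >= step")
  gr <- fragmentRanges(fs)
  if (is.null(genome)) {
    genome <- seqinfo(gr)
    if (any(is.na(seqlengths(genome))))
      stop("genome lengths unknown; supply a genome table")
  }
  gr <- .applyGenome(gr, genome)
  mids0 <- start(fragmentMidpoints(gr)) - 1L   # 0-based midpoint positions
  chrom <- as.character(seqnames(gr))
  sl <- seqlengths(genome)
  vals <- lapply(names(sl), function(ch) {
    n <- as.integer(ceiling(sl[[ch]] / step))
    m <- mids0[chrom == ch]
    if (length(m) == 0L) return(numeric(n))
    # midpoint m lies in windows starting at step-multiples s with
    # m - window < s <= m; convert to record indices and accumulate
    lo <- pmax(1L, (m - window) %/% step + 2L)
    hi <- pmin(n, m %/% step + 1L)
    keep <- lo <= hi
    d <- numeric(n + 1L)
    if (any(keep)) {
      add <- tabulate(lo[keep], nbins = n + 1L)
      subP <- tabulate(hi[keep] + 1L, nbins = n + 1L)
      d <- add - subP
    }
    cumsum(d)[seq_len(n)]
  })
  names(vals) <- names(sl)
  .newTrack(genome, window, step, vals, "raw", "frenter",
            nFragments = length(gr))
}

#' Normalize a track
#'
#' `"CPM"` multiplies every value by `1e6 / nFragments` of the originating
#' library. `"quantile"` rank-matches the track's non-zero values onto the
#' reference track's non-zero value distribution (ties averaged); zeros stay
#' zero, so sparsity does not distort the upper tail.
#'
#' @param track a raw [CoverageTrack].
#' @param method `"CPM"` or `"quantile"`.
#' @param reference reference [CoverageTrack] for quantile normalization.
#' @return a normalized [CoverageTrack].
#' @export
normalizeTrack <- function(track, method = c("CPM", "quantile"),
                           reference = NULL) {
  method <- match.arg(method)
  vals <- as.list(track@values)
  if (method == "CPM") {
    n <- track@nFragments
    if (is.na(n) || n <= 0)
      stop("CPM normalization requires a library with > 0 fragments")
    vals <- lapply(vals, function(v) v * 1e6 / n)
  } else {
    if (is.null(reference)) stop("quantile normalization needs a reference")
    refv <- unlist(as.list(reference@values), use.names = FALSE)
    refnz <- sort(refv[refv != 0])
    if (length(refnz) == 0L) stop("reference has no non-zero values")
    flat <- unlist(vals, use.names = FALSE)
    nz <- which(flat != 0)
    if (length(nz)) {
      r <- rank(flat[nz], ties.method = "average")
      p <- if (length(nz) == 1L) 0.5 else (r - 1) / (length(nz) - 1)
      flat[nz] <- quantile(refnz, probs = p, names = FALSE, type = 7)
      lens <- lengths(vals)
      vals <- split(flat, rep(seq_along(vals), lens))
      names(vals) <- names(track@values)
    }
  }
  .newTrack(track@genome, track@binWidth, track@step, vals, method,
            track@kind, track@nFragments)
}

#' Subtract a control track
#'
#' Elementwise difference of two tracks with identical geometry and
#' normalization; negative values are retained (the result is a signed
#' track).
#'
#' @param track,control [CoverageTrack] objects with identical genome,
#'   `binWidth`, `step` and normalization.
#' @return a [CoverageTrack] with normalization `"subtracted"`.
#' @export
subtractControl <- function(track, control) {
  if (!identical(seqlengths(track@genome), seqlengths(control@genome)) ||
      track@binWidth != control@binWidth || track@step != control@step ||
      track@normalization != control@normalization)
    stop("track and control geometry/normalization mismatch")
  vals <- mapply(function(a, b) a - b, as.list(track@values),
                 as.list(control@values), SIMPLIFY = FALSE)
  .newTrack(track@genome, track@binWidth, track@step, vals, "subtracted",
            track@kind, track@nFragments)
}

#' Write a track as bedGraph
#'
#' One record per step-grid bin; zero-value bins are omitted. The final bin of
#' a chromosome is truncated at the chromosome end.
#'
#' @param track a [CoverageTrack].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeBedGraph <- function(track, file) {
  sl <- seqlengths(track@genome)
  parts <- lapply(names(sl), function(ch) {
    v <- track@values[[ch]]
    idx <- which(v != 0)
    if (length(idx) == 0L) return(NULL)
    start1 <- (idx - 1L) * track@step + 1L
    end1 <- pmin(idx * track@step, sl[[ch]])
    GRanges(ch, IRanges(start1, end1), score = v[idx],
            seqinfo = track@genome)
  })
  gr <- do.call(c, c(parts[!vapply(parts, is.null, logical(1))],
                     list(GRanges(seqinfo = track@genome))))
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Read a bedGraph written by [writeBedGraph()] back into a track
#'
#' @param file bedGraph path.
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param binWidth,step,kind,normalization track geometry (must match what
#'   the file was written with).
#' @return a [CoverageTrack].
#' @export
readBedGraphTrack <- function(file, genome, binWidth = 10L, step = binWidth,
                              kind = "coverage", normalization = "raw") {
  gr <- rtracklayer::import(file, format = "bedGraph")
  gr <- .applyGenome(gr, genome)
  sl <- seqlengths(genome)
  vals <- lapply(names(sl), function(ch) numeric(ceiling(sl[[ch]] / step)))
  names(vals) <- names(sl)
  if (length(gr)) {
    idx <- (start(gr) - 1L) %/% step + 1L
    ch <- as.character(seqnames(gr))
    for (i in seq_along(gr)) vals[[ch[i]]][idx[i]] <- gr$score[i]
  }
  .newTrack(genome, binWidth, step, vals, normalization, kind)
}

# Track values at 0-based genomic positions (NA outside the chromosome).
.trackValueAt <- function(track, chrom, pos0) {
  v <- track@values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  n <- length(v)
  idx <- pos0 %/% track@step + 1
  out <- rep(NA_real_, length(pos0))
  ok <- !is.na(pos0) & pos0 >= 0 & idx <= n
  out[ok] <- v[idx[ok]]
  out
}
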