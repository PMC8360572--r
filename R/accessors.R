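# Accessor and show methods for the core classes.

#' @rdname FragmentSet-class
setMethod("fragmentRanges", "FragmentSet", function(x) x@fragments)

#' @rdname FragmentSet-class
setMethod("libraryId", "FragmentSet", function(x) x@libraryId)

#' @rdname FragmentSet-class
setMethod("totalCount", "FragmentSet", function(x) length(x@fragments))

#' @rdname FragmentSet-class
setMethod("length", "FragmentSet", function(x) length(x@fragments))

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet '", object@libraryId, "': ", length(object),
      " fragments on ", length(seqlevels(object@fragments)),
      " chromosome(s)\n", sep = "")
  if (length(object)) {
    w <- width(object@fragments)
    cat("  width: min ", min(w), ", median ", median(w), ", max ", max(w),
        " bp\n", sep = "")
  }
})

#' @rdname CoverageTrack-class
setMethod("trackGenome", "CoverageTrack", function(x) x@genome)

#' @rdname CoverageTrack-class
setMethod("binWidth", "CoverageTrack", function(x) x@binWidth)

#' @rdname CoverageTrack-class
setMethod("trackStep", "CoverageTrack", function(x) x@step)

#' @rdname CoverageTrack-class
setMethod("trackKind", "CoverageTrack", function(x) x@kind)

#' @rdname CoverageTrack-class
setMethod("trackNormalization", "CoverageTrack",
  function(x) x@normalization)

#' @rdname CoverageTrack-class
setMethod("trackValues", "CoverageTrack", function(x, chrom = NULL) {
  if (is.null(chrom)) return(x@values)
  if (!chrom %in% names(x@values))
    stop("unknown chromosome: ", chrom)
  x@values[[chrom]]
})

setMethod("show", "CoverageTrack", function(object) {
  nb <- sum(vapply(object@values, length, integer(1)))
  cat("CoverageTrack (", object@kind, ", ", object@normalization, "): ",
      length(object@values), " chromosome(s), ", nb, " records, window ",
      object@binWidth, " bp / step ", object@step, " bp\n", sep = "")
})

#' @rdname SegmentSet-class
setMethod("peakRanges", "SegmentSet", function(x) x@peaks)

#' @rdname SegmentSet-class
setMethod("genomeFraction", "SegmentSet", function(x) x@genomeFraction)

#' @rdname SegmentSet-class
setMethod("meanWidth", "SegmentSet", function(x) x@meanWidth)

#' @rdname SegmentSet-class
setMethod("segmentParams", "SegmentSet", function(x) x@params)

#' @rdname SegmentSet-class
setMethod("length", "SegmentSet", function(x) length(x@peaks))

setMethod("show", "SegmentSet", function(object) {
  cat("SegmentSet: ", length(object@peaks), " peaks (bc = ", object@params@bc,
      ", scale = ", object@params@scale, "), genome fraction ",
      signif(object@genomeFraction * 100, 3), "%, mean width ",
      signif(object@meanWidth, 4), " bp\n", sep = "")
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams: bc ", object@bc, ", windows ", object@minWindow,
      "-", object@maxWindow, " bp, merge gap ", object@mergeGap,
      " bp, scale ", object@scale, "\n", sep = "")
})

setMethod("show", "ScaleStats", function(object) {
  nsup <- sum(vapply(object@support, sum, numeric(1)))
  cat("ScaleStats over ", nsup, " support bins: mean ",
      signif(object@mean, 4), ", sd ", signif(object@sd, 4), ", mad ",
      signif(object@mad, 4), "\n", sep = "")
})

#' @rdname GeneModelSet-class
setMethod("geneBodies", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
setMethod("cdsParts", "GeneModelSet", function(x) x@cds)

#' @rdname GeneModelSet-class
setMethod("length", "GeneModelSet", function(x) length(x@genes))

#' @rdname GeneModelSet-class
setMethod("tssSites", "GeneModelSet", function(x) {
  g <- x@genes
  strand(g)[strand(g) == "*"] <- "+"
  tss <- resize(g, width = 1L, fix = "start")
  names(tss) <- names(x@genes)
  tss
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet: ", length(object@genes), " genes, ",
      length(object@cds), " CDS intervals\n", sep = "")
})

#' @rdname MotifSiteSet-class
setMethod("siteRanges", "MotifSiteSet", function(x) x@sites)

#' @rdname MotifSiteSet-class
setMethod("motifOf", "MotifSiteSet", function(x) x@motif)

#' @rdname MotifSiteSet-class
setMethod("length", "MotifSiteSet", function(x) length(x@sites))

setMethod("show", "MotifModel", function(object) {
  if (object@kind == "oligo") {
    cat("MotifModel ", object@name, " (oligo): ", object@consensus, "\n",
        sep = "")
  } else {
    cat("MotifModel ", object@name, " (dyad): ", object@leftWord, " N{",
        object@spacerMin, ",", object@spacerMax, "} ", object@rightWord,
        "\n", sep = "")
  }
})

setMethod("show", "MotifSiteSet", function(object) {
  cat("MotifSiteSet for ", object@motif@name, ": ", length(object@sites),
      " sites\n", sep = "")
})

setMethod("show", "ChromatinTemplate", function(object) {
  cat("ChromatinTemplate: ", length(object@sequences), " chromosome(s), ",
      sum(lengths(object@sequences)), " bp; ", length(object@geneModels),
      " genes, ", length(object@tfSites), " TF sites, ",
      length(object@nucleosomes), " nucleosomes, ", length(object@repeats),
      " repeats\n", sep = "")
})
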