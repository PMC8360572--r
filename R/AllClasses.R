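#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import GenomeInfoDb
#' @import Biostrings
#' @importFrom stats rpois rnorm runif rlnorm pnorm setNames
#' @importFrom utils read.table write.table
NULL

#' FragmentSet: aligned paired-end fragment intervals from one library
#'
#' Container for the aligned-fragment population of a sequencing library.
#' Fragments are stored as an unstranded [GenomicRanges::GRanges] (duplex
#' molecules carry no strand); the library identifier travels with the set.
#'
#' @slot fragments `GRanges` of fragment intervals (1-based, closed; BED
#'   files are converted at the boundary).
#' @slot libraryId single character library label.
#' @export
setClass("FragmentSet",
  representation(fragments = "GRanges", libraryId = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@libraryId) != 1L)
      msg <- c(msg, "libraryId must be a single string")
    sl <- seqlengths(object@fragments)
    if (length(object@fragments) && any(!is.na(sl))) {
      gr <- object@fragments
      lens <- sl[as.character(seqnames(gr))]
      bad <- !is.na(lens) & (start(gr) < 1L | end(gr) > lens)
      if (any(bad))
        msg <- c(msg, "fragments extend beyond chromosome bounds")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' CoverageTrack: binned signal over a genome
#'
#' A genome-wide signal track on a regular step grid. For `kind = "coverage"`
#' each bin holds the mean per-base fragment depth in a `binWidth` window
#' (`step == binWidth`). For `kind = "frenter"` each grid record anchored at a
#' multiple of `step` holds the count of fragment midpoints in the
#' `binWidth`-wide window starting there (windows overlap, records do not).
#'
#' @slot genome [GenomeInfoDb::Seqinfo] describing the chromosomes.
#' @slot binWidth window width in bp.
#' @slot step grid step in bp (`ceiling(length/step)` values per chromosome).
#' @slot values named `SimpleList` of numeric vectors, one per chromosome.
#' @slot normalization one of `"raw"`, `"CPM"`, `"quantile"`, `"subtracted"`.
#' @slot kind `"coverage"` or `"frenter"`.
#' @slot nFragments fragment count of the originating library (for CPM).
#' @export
setClass("CoverageTrack",
  representation(genome = "Seqinfo", binWidth = "integer", step = "integer",
    values = "SimpleList", normalization = "character", kind = "character",
    nFragments = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@step < 1L || object@binWidth < object@step)
      msg <- c(msg, "need binWidth >= step >= 1")
    if (!object@kind %in% c("coverage", "frenter"))
      msg <- c(msg, "kind must be 'coverage' or 'frenter'")
    if (!object@normalization %in% c("raw", "CPM", "quantile", "subtracted"))
      msg <- c(msg, "unknown normalization")
    sl <- seqlengths(object@genome)
    if (!identical(names(object@values), names(sl)))
      msg <- c(msg, "values must be named by the genome's chromosomes")
    else {
      nbin <- vapply(object@values, length, integer(1))
      if (any(nbin != as.integer(ceiling(sl / object@step))))
        msg <- c(msg, "each chromosome needs ceiling(length/step) values")
      if (object@normalization %in% c("raw", "CPM") &&
          any(vapply(object@values, function(v) any(v < 0), logical(1))))
        msg <- c(msg, "raw/CPM values must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' ScaleStats: dispersion statistics over the non-zero support of a track
#'
#' Sample mean, standard deviation (n-1 denominator) and plain median
#' absolute deviation computed over the support bins (bins where the support
#' source track is non-zero), used to standardize tracks before segmentation.
#'
#' @slot mean,sd,mad scalar statistics over support bins.
#' @slot support named `SimpleList` of logical vectors flagging support bins.
#' @export
setClass("ScaleStats",
  representation(mean = "numeric", sd = "numeric", mad = "numeric",
    support = "SimpleList"),
  validity = function(object) {
    if (object@sd < 0 || object@mad < 0) "sd and mad must be >= 0" else TRUE
  }
)

#' SegmentationParams: biological-cutoff segmentation parameters
#'
#' @slot bc biological cutoff, in multiples of the track's scale statistic.
#' @slot minWindow,maxWindow candidate segment widths in bp (default 20-120).
#' @slot mergeGap book-ended/adjacent peaks separated by <= mergeGap bp are
#'   merged into final peaks (default 1).
#' @slot scale `"sd"` or `"mad"`.
#' @export
setClass("SegmentationParams",
  representation(bc = "numeric", minWindow = "integer", maxWindow = "integer",
    mergeGap = "integer", scale = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@bc <= 0) msg <- c(msg, "bc must be > 0")
    if (object@minWindow < 1L || object@minWindow > object@maxWindow)
      msg <- c(msg, "need 0 < minWindow <= maxWindow")
    if (object@mergeGap < 0L) msg <- c(msg, "mergeGap must be >= 0")
    if (!object@scale %in% c("sd", "mad"))
      msg <- c(msg, "scale must be 'sd' or 'mad'")
    if (is.null(msg)) TRUE else msg
  }
)

#' SegmentSet: called peaks with heights and scores
#'
#' Peaks from biological-cutoff segmentation. The ranges carry `meanHeight`
#' (mean raw track value), `tStat` (mean standardized value times the square
#' root of the number of grid records) and `pValue` (one-sided normal tail of
#' the t statistic, carried to fill the six-column output convention).
#'
#' @slot peaks sorted, non-overlapping `GRanges` with score columns.
#' @slot params the [SegmentationParams] used.
#' @slot genomeFraction total peak bp divided by genome bp.
#' @slot meanWidth mean peak width in bp (`NA` when no peaks were called).
#' @export
setClass("SegmentSet",
  representation(peaks = "GRanges", params = "SegmentationParams",
    genomeFraction = "numeric", meanWidth = "numeric"),
  validity = function(object) {
    msg <- NULL
    req <- c("meanHeight", "tStat", "pValue")
    if (length(object@peaks) && !all(req %in% names(mcols(object@peaks))))
      msg <- c(msg, "peaks need meanHeight, tStat and pValue columns")
    if (object@genomeFraction < 0 || object@genomeFraction > 1)
      msg <- c(msg, "genomeFraction must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' GeneModelSet: gene bodies with CDS intervals
#'
#' Minimal gene annotation: gene bodies as a named, stranded `GRanges` and
#' CDS intervals tagged by `gene_id`. The TSS of a gene is its 5' boundary in
#' gene orientation; strand `"."`/`"*"` is treated as `"+"`.
#'
#' @slot genes `GRanges` of gene bodies, names are gene ids.
#' @slot cds `GRanges` of CDS intervals with a `gene_id` metadata column.
#' @export
setClass("GeneModelSet",
  representation(genes = "GRanges", cds = "GRanges"),
  validity = function(object) {
    msg <- NULL
    if (length(object@genes) && is.null(names(object@genes)))
      msg <- c(msg, "genes must be named by gene id")
    if (length(object@genes) && anyDuplicated(names(object@genes)))
      msg <- c(msg, "gene ids must be unique")
    if (length(object@cds)) {
      if (!"gene_id" %in% names(mcols(object@cds)))
        msg <- c(msg, "cds needs a gene_id column")
      else {
        gid <- mcols(object@cds)$gene_id
        if (!all(gid %in% names(object@genes)))
          msg <- c(msg, "cds gene_id must match a gene")
        else {
          g <- object@genes[gid]
          ok <- as.character(seqnames(object@cds)) ==
                  as.character(seqnames(g)) &
                start(object@cds) >= start(g) & end(object@cds) <= end(g)
          if (!all(ok)) msg <- c(msg, "cds intervals must lie within gene body")
        }
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' MotifModel: IUPAC oligo or spaced dyad consensus
#'
#' @slot name motif family name (e.g. `om015`, `dym33`).
#' @slot kind `"oligo"` (contiguous consensus) or `"dyad"` (two words with a
#'   spacer range).
#' @slot consensus IUPAC consensus string (oligo).
#' @slot leftWord,rightWord dyad half-words (IUPAC).
#' @slot spacerMin,spacerMax inclusive spacer range in bp (dyad).
#' @export
setClass("MotifModel",
  representation(name = "character", kind = "character",
    consensus = "character", leftWord = "character", rightWord = "character",
    spacerMin = "integer", spacerMax = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("oligo", "dyad"))
      msg <- c(msg, "kind must be 'oligo' or 'dyad'")
    if (object@kind == "oligo") {
      if (nchar(object@consensus) < 4L)
        msg <- c(msg, "oligo consensus must be >= 4 bp")
      if (!.validIupac(object@consensus))
        msg <- c(msg, "invalid IUPAC character in consensus")
    } else {
      if (nchar(object@leftWord) < 3L || nchar(object@rightWord) < 3L)
        msg <- c(msg, "dyad words must be >= 3 bp")
      if (object@spacerMin > object@spacerMax || object@spacerMin < 0L)
        msg <- c(msg, "need 0 <= spacerMin <= spacerMax")
      if (!.validIupac(object@leftWord) || !.validIupac(object@rightWord))
        msg <- c(msg, "invalid IUPAC character in dyad word")
    }
    if (is.null(msg)) TRUE else msg
  }
)

.validIupac <- function(x) {
  nchar(x) > 0L &&
    all(strsplit(toupper(x), "")[[1]] %in% names(IUPAC_CODE_MAP))
}

#' MotifSiteSet: genomic matches of one motif model
#'
#' Stranded match sites of a [MotifModel]. Each site records the matched
#' sequence in motif orientation (`matchSeq`) and is named by the convention
#' `name_motifConsensus_ExactLocalSeq`.
#'
#' @slot sites `GRanges` with strand and a `matchSeq` metadata column.
#' @slot motif the [MotifModel] that was scanned.
#' @export
setClass("MotifSiteSet",
  representation(sites = "GRanges", motif = "MotifModel"),
  validity = function(object) {
    if (length(object@sites) &&
        !"matchSeq" %in% names(mcols(object@sites)))
      "sites need a matchSeq column" else TRUE
  }
)

#' ChromatinTemplate: synthetic genome with occupancy ground truth
#'
#' A simulated chromatin template: genome sequence, gene models with
#' expression values, nucleosome cores, protein-bound (TF) sites carrying an
#' occupancy probability and a planted motif consensus, and repeat intervals.
#' Used by [simulateDigest()] to generate fragment populations with known
#' truth for recovery scoring.
#'
#' @slot sequences `DNAStringSet`, one entry per chromosome.
#' @slot geneModels [GeneModelSet] of the synthetic genes.
#' @slot expression named numeric steady-state expression per gene.
#' @slot nucleosomes `GRanges` of 147 bp cores with `occupancy` and
#'   `jitterSd` columns.
#' @slot tfSites `GRanges` with `occupancy` (pi), `class` (promoter or
#'   intergenic_enhancer), `motif` and `consensus` columns.
#' @slot repeats `GRanges` of annotated repeat intervals.
#' @export
setClass("ChromatinTemplate",
  representation(sequences = "DNAStringSet", geneModels = "GeneModelSet",
    expression = "numeric", nucleosomes = "GRanges", tfSites = "GRanges",
    repeats = "GRanges"),
  validity = function(object) {
    msg <- NULL
    if (length(object@tfSites)) {
      occ <- mcols(object@tfSites)$occupancy
      if (is.null(occ) || any(occ < 0 | occ > 1))
        msg <- c(msg, "tfSites need occupancy in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
  }
)
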