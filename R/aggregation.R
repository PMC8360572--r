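# Metagene, metapeak and expression-quintile profiles; footprint
# classification relative to gene annotation.

# Source genomic 0-based positions for one feature rescaled to `out` points,
# plus real-bp flanks, oriented 5'->3' on the feature strand.
.profilePositions <- function(start0, end0, strandChar, out, flank) {
  L <- end0 - start0
  if (strandChar == "-") {
    up <- (end0 - 1 + flank) - 0:(flank - 1)           # far -> near TSS
    body <- (end0 - 1) - floor((0:(out - 1)) * L / out)
    down <- (start0 - 1) - 0:(flank - 1)               # near -> far TTS
  } else {
    up <- (start0 - flank) + 0:(flank - 1)
    body <- start0 + floor((0:(out - 1)) * L / out)
    down <- end0 + 0:(flank - 1)
  }
  if (flank > 0) c(up, body, down) else body
}

.aggregateProfile <- function(track, feats, out, flank) {
  npos <- out + 2L * flank
  total <- numeric(npos)
  count <- numeric(npos)
  chs <- as.character(seqnames(feats))
  st <- start(feats) - 1L
  en <- end(feats)
  sd_ <- as.character(strand(feats))
  sd_[sd_ == "*"] <- "+"
  for (i in seq_along(feats)) {
    pos <- .profilePositions(st[i], en[i], sd_[i], out, flank)
    v <- .trackValueAt(track, chs[i], pos)
    ok <- !is.na(v)
    total[ok] <- total[ok] + v[ok]
    count <- count + ok
  }
  prof <- total / count
  prof[count == 0] <- NA_real_
  prof
}

#' Metagene profile
#'
#' Each gene body is linearly rescaled to `bodyLength` positions (position j
#' of the body reads the track at source base `floor(j * L / bodyLength)`,
#' nearest-source-base lookup, no interpolation); flanks are taken in real bp
#' from the gene boundaries. Minus-strand genes are reversed so the profile
#' runs 5' flank, body, 3' flank. The profile is the per-position mean over
#' genes; positions falling outside a chromosome are excluded from the mean.
#' Genes shorter than 2 bp are skipped with a warning.
#'
#' @param track a [CoverageTrack].
#' @param gm a [GeneModelSet] (or a stranded `GRanges` of gene bodies).
#' @param bodyLength rescaled body length in positions (default 2000).
#' @param flank flank length in real bp on each side (default 1500).
#' @return numeric vector of length `flank + bodyLength + flank`, with a
#'   `region` attribute marking `upstream`/`body`/`downstream` positions.
#' @export
metageneProfile <- function(track, gm, bodyLength = 2000L, flank = 1500L) {
  genes <- if (is(gm, "GeneModelSet")) geneBodies(gm) else gm
  if (length(genes) == 0L) stop("no genes supplied")
  short <- width(genes) < 2L
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than 2 bp skipped")
    genes <- genes[!short]
  }
  prof <- .aggregateProfile(track, genes, bodyLength, flank)
  attr(prof, "region") <- rep(c("upstream", "body", "downstream"),
                              c(flank, bodyLength, flank))
  prof
}

#' Metapeak profile
#'
#' The mean input peak width (rounded) defines a single metapeak size; each
#' input interval is rescaled to it and flanks are taken in real bp relative
#' to the metapeak boundary. Inputs are treated as unstranded.
#'
#' @param track a [CoverageTrack].
#' @param centers `GRanges` of input intervals (e.g. binding-site peaks).
#' @param flank flank in real bp (default 1500).
#' @return numeric profile with attributes `metapeakSize` and `region`.
#' @export
metapeakProfile <- function(track, centers, flank = 1500L) {
  if (length(centers) == 0L) stop("no input intervals supplied")
  size <- as.integer(round(mean(width(centers))))
  gr <- granges(centers)
  strand(gr) <- "+"
  prof <- .aggregateProfile(track, gr, size, flank)
  attr(prof, "metapeakSize") <- size
  attr(prof, "region") <- rep(c("upstream", "metapeak", "downstream"),
                              c(flank, size, flank))
  prof
}

#' Assign expression quintiles
#'
#' Genes are ranked by descending expression (missing values are treated as
#' 0), stable-sorted by gene id on ties; quintile 1 is the highest-expression
#' fifth and group sizes differ by at most 1.
#'
#' @param expression named numeric vector of expression values.
#' @param geneIds gene ids to rank (default: names of `expression`).
#' @return named integer vector of quintiles (1-5) in `geneIds` order.
#' @export
expressionQuintiles <- function(expression, geneIds = names(expression)) {
  n <- length(geneIds)
  if (n < 5L) stop("need at least 5 genes to form quintiles")
  ex <- expression[geneIds]
  ex[is.na(ex)] <- 0
  ord <- order(-ex, geneIds)           # stable on ties via gene id
  sizes <- rep(n %/% 5L, 5L)
  extra <- n %% 5L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- integer(n)
  q[ord] <- rep(1:5, sizes)
  setNames(q, geneIds)
}

#' TSS-anchored profiles by expression quintile
#'
#' Mean strand-oriented coverage in a window around the TSS, one profile per
#' expression quintile (quintile 1 = highest expression).
#'
#' @param track a [CoverageTrack].
#' @param gm a [GeneModelSet].
#' @param expression named numeric expression vector (genes missing from it
#'   are treated as expression 0).
#' @param window half-window in bp around the TSS (default 1000); profiles
#'   cover positions `-window .. window - 1` relative to the TSS.
#' @return a 5 x (2*window) matrix, rows `Q1`..`Q5`, columns the relative
#'   positions.
#' @export
quintileProfiles <- function(track, gm, expression, window = 1000L) {
  genes <- geneBodies(gm)
  q <- expressionQuintiles(expression, names(genes))
  tss <- tssSites(gm)
  # a width-2*window feature starting `window` bp upstream of the TSS;
  # rescale factor 1 (out = width) makes this a plain oriented window
  anchors <- suppressWarnings(promoters(tss, upstream = window,
                                        downstream = window))
  out <- matrix(NA_real_, nrow = 5L, ncol = 2L * window,
                dimnames = list(paste0("Q", 1:5),
                                as.character(seq(-window, window - 1L))))
  for (k in 1:5) {
    sel <- anchors[q[names(genes)] == k]
    out[k, ] <- .aggregateProfile(track, sel, 2L * window, 0L)
  }
  out
}

#' @importFrom GenomicRanges promoters
NULL

#' Classify footprints relative to genes
#'
#' Each footprint is assigned exactly one category by priority: overlaps a
#' CDS interval -> `coding`; overlaps a gene body but no CDS -> `gene_other`;
#' lies within `flank` bp of a gene boundary -> `flanking`; otherwise
#' `intergenic`. Categories are mutually exclusive and the counts sum to the
#' number of footprints.
#'
#' @param mfs a [SegmentSet] or merged `GRanges` of footprints.
#' @param gm a [GeneModelSet].
#' @param flank flanking distance in bp (default 2000).
#' @return named integer counts over the four categories, with the per-peak
#'   factor attached as attribute `category`.
#' @export
classifyFootprints <- function(mfs, gm, flank = 2000L) {
  gr <- if (is(mfs, "SegmentSet")) peakRanges(mfs) else mfs
  genes <- geneBodies(gm)
  cds <- cdsParts(gm)
  inCds <- overlapsAny(gr, cds, ignore.strand = TRUE)
  inGene <- overlapsAny(gr, genes, ignore.strand = TRUE)
  nearGene <- overlapsAny(gr, suppressWarnings(
    GenomicRanges::trim(genes + flank)), ignore.strand = TRUE)
  cat <- ifelse(inCds, "coding",
         ifelse(inGene, "gene_other",
         ifelse(nearGene, "flanking", "intergenic")))
  lv <- c("coding", "gene_other", "flanking", "intergenic")
  cat <- factor(cat, levels = lv)
  counts <- as.integer(table(cat))
  names(counts) <- lv
  attr(counts, "category") <- cat
  counts
}

#' Write a profile as two-column TSV
#'
#' @param profile numeric profile (from [metageneProfile()] etc.).
#' @param file output path.
#' @param positions relative positions; defaults to `seq_along(profile)`.
#' @return `file`, invisibly.
#' @export
writeProfile <- function(profile, file, positions = seq_along(profile)) {
  write.table(data.frame(position = positions, value = as.numeric(profile)),
              file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
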