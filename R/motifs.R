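# IUPAC oligo / spaced-dyad motif models: scanning, enrichment folds, TSS
# positional statistics, merged motif contigs and per-motif catalog pages.
# De-novo discovery is delegated to external tools; this module scans and
# evaluates given motif models.

#' Construct a motif model
#'
#' @param name motif family name (e.g. `"om015"`, `"dym33"`).
#' @param kind `"oligo"` or `"dyad"`.
#' @param consensus IUPAC consensus (oligo kind).
#' @param leftWord,rightWord dyad half-words (dyad kind).
#' @param spacerMin,spacerMax inclusive spacer range in bp (dyad kind).
#' @return a [MotifModel].
#' @export
motifModel <- function(name, kind = c("oligo", "dyad"), consensus = "",
                       leftWord = "", rightWord = "", spacerMin = 0L,
                       spacerMax = spacerMin) {
  kind <- match.arg(kind)
  new("MotifModel", name = name, kind = kind,
      consensus = toupper(consensus), leftWord = toupper(leftWord),
      rightWord = toupper(rightWord), spacerMin = as.integer(spacerMin),
      spacerMax = as.integer(spacerMax))
}

#' Read motif models from a TSV
#'
#' Columns (tab-separated, with header): `name`, `kind`, `consensus` (oligo)
#' or `left`, `right`, `smin`, `smax` (dyad). Unused columns may be empty.
#'
#' @param file path to the table.
#' @return a list of [MotifModel]s.
#' @export
readMotifTable <- function(file) {
  tab <- read.table(file, sep = "\t", header = TRUE,
                    colClasses = "character", fill = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    if (tab$kind[i] == "oligo") {
      motifModel(tab$name[i], "oligo", consensus = tab$consensus[i])
    } else {
      motifModel(tab$name[i], "dyad", leftWord = tab$left[i],
                 rightWord = tab$right[i],
                 spacerMin = as.integer(tab$smin[i]),
                 spacerMax = as.integer(tab$smax[i]))
    }
  })
}

# Consensus display string for naming: oligo consensus, or left+Ns+right for
# the realized spacer.
.consensusLabel <- function(model, spacer = NULL) {
  if (model@kind == "oligo") return(model@consensus)
  paste0(model@leftWord, strrep("N", spacer), model@rightWord)
}

.scanPatterns <- function(model) {
  if (model@kind == "oligo") {
    list(list(pattern = model@consensus, spacer = NA_integer_))
  } else {
    lapply(model@spacerMin:model@spacerMax, function(s)
      list(pattern = paste0(model@leftWord, strrep("N", s),
                            model@rightWord), spacer = s))
  }
}

#' Scan a genome for motif matches
#'
#' All matches on both strands are reported under IUPAC semantics; overlaps
#' and palindromic double-hits are retained. Dyads match
#' `leftWord N^s rightWord` for every spacer `s` in the model's range. Sites
#' are named by the BED convention `name_motifConsensus_ExactLocalSeq`, where
#' the local sequence is the match read in motif orientation.
#'
#' @param sequences named `DNAStringSet` genome.
#' @param model a [MotifModel].
#' @param regions optional `GRanges`; when supplied, only matches fully
#'   inside these regions are kept.
#' @return a [MotifSiteSet].
#' @export
scanMotif <- function(sequences, model, regions = NULL) {
  genome <- genomeOf(sequences)
  pats <- .scanPatterns(model)
  parts <- list()
  for (p in pats) {
    pat <- DNAString(p$pattern)
    label <- .consensusLabel(model, p$spacer)
    for (std in c("+", "-")) {
      q <- if (std == "+") pat else reverseComplement(pat)
      hits <- vmatchPattern(q, sequences, fixed = FALSE)
      for (ch in names(sequences)) {
        ir <- hits[[ch]]
        if (length(ir) == 0L) next
        gr <- GRanges(ch, ir, strand = std, seqinfo = genome)
        seqs <- as.character(Biostrings::extractAt(sequences[[ch]], ir))
        if (std == "-")
          seqs <- as.character(reverseComplement(DNAStringSet(seqs)))
        mcols(gr)$matchSeq <- seqs
        mcols(gr)$label <- label
        parts[[length(parts) + 1L]] <- gr
      }
    }
  }
  sites <- if (length(parts)) sort(do.call(c, unname(parts)))
           else {
             g <- GRanges(seqinfo = genome)
             mcols(g)$matchSeq <- character(0)
             mcols(g)$label <- character(0)
             g
           }
  if (!is.null(regions) && length(sites))
    sites <- sites[overlapsAny(sites, regions, type = "within",
                               ignore.strand = TRUE)]
  names(sites) <- if (length(sites))
    paste(model@name, mcols(sites)$label, mcols(sites)$matchSeq, sep = "_")
    else character(0)
  mcols(sites)$label <- NULL
  new("MotifSiteSet", sites = sites, motif = model)
}

#' Write motif sites as BED6
#'
#' Names follow the `name_motifConsensus_ExactLocalSeq` convention; the score
#' column is 0 and strand records motif orientation.
#'
#' @param x a [MotifSiteSet].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeMotifSites <- function(x, file) {
  gr <- siteRanges(x)
  out <- granges(gr)
  names(out) <- names(gr)
  mcols(out)$score <- 0
  writeBed(out, file)
}

#' Expand regions to a minimum size
#'
#' Regions narrower than `minSize` are symmetrically padded to `minSize`
#' (the extra base goes on the left for odd deficits) and clipped to
#' chromosome bounds; wider regions are unchanged. Used to retain
#' sub-minimum peaks as motif-discovery input.
#'
#' @param regions a `GRanges`.
#' @param minSize minimum width in bp (default 24).
#' @return a `GRanges` of width >= `minSize` (except where clipped).
#' @export
expandMinSize <- function(regions, minSize = 24L) {
  stopifnot(minSize > 0L)
  deficit <- pmax(0L, minSize - width(regions))
  left <- as.integer(ceiling(deficit / 2))
  right <- deficit - left
  out <- regions
  suppressWarnings({
    start(out) <- start(regions) - left
    end(out) <- end(out) + right
    out <- GenomicRanges::trim(out)
  })
  out
}

#' Motif enrichment fold in a target versus a background space
#'
#' A site is assigned to the target iff its midpoint falls inside it; the
#' fold is the density ratio `(nTarget/bpTarget) / (nSpace/bpSpace)`. The
#' merged target must be contained in the space, and sites are expected to
#' have been scanned over (at least) the space.
#'
#' @param sites a [MotifSiteSet].
#' @param target merged `GRanges` (e.g. ChIP binding sites).
#' @param space merged `GRanges` background (e.g. whole mappable genome or
#'   promoter space).
#' @return a list with `fold`, `nTarget`, `nSpace`, `bpTarget`, `bpSpace`.
#' @export
enrichmentFold <- function(sites, target, space) {
  target <- mergeIntervals(target)
  space <- mergeIntervals(space)
  if (overlapBp(target, space) != sum(as.numeric(width(target))))
    stop("target must be contained in space")
  bpTarget <- sum(as.numeric(width(target)))
  bpSpace <- sum(as.numeric(width(space)))
  if (bpTarget == 0 || bpSpace == 0) stop("empty target or space")
  mids <- fragmentMidpoints(siteRanges(sites))
  nTarget <- sum(overlapsAny(mids, target, ignore.strand = TRUE))
  nSpace <- sum(overlapsAny(mids, space, ignore.strand = TRUE))
  if (nSpace == 0L) stop("no sites in the background space")
  list(fold = (nTarget / bpTarget) / (nSpace / bpSpace),
       nTarget = nTarget, nSpace = nSpace,
       bpTarget = bpTarget, bpSpace = bpSpace)
}

#' Whole-genome background space
#'
#' The full genome as merged intervals, optionally restricted to a
#' mappability BED (the operational stand-in for the "mappable" genome).
#'
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param mappable optional `GRanges` of mappable intervals.
#' @return a merged `GRanges`.
#' @export
genomeSpace <- function(genome, mappable = NULL) {
  whole <- GRanges(seqnames(genome), IRanges(1L, seqlengths(genome)),
                   seqinfo = genome)
  if (is.null(mappable)) return(whole)
  mergeIntervals(.applyGenome(mappable, genome))
}

#' Non-ORF promoter space
#'
#' Strand-oriented windows of up to `upstream` bp directly upstream of each
#' TSS, truncated where they would run into any CDS interval of any gene
#' (keeping the TSS-proximal portion), clipped at chromosome bounds and
#' merged.
#'
#' @param gm a [GeneModelSet].
#' @param upstream window length in bp (default 3000).
#' @return a merged `GRanges` of promoter space.
#' @export
promoterSpace <- function(gm, upstream = 3000L) {
  genes <- geneBodies(gm)
  cds <- reduce(granges(cdsParts(gm)), ignore.strand = TRUE)
  std <- as.character(strand(genes))
  std[std == "*"] <- "+"
  parts <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    if (std[i] == "+") {
      s1 <- start(genes)[i] - upstream
      e1 <- start(genes)[i] - 1L
      anchor <- e1
    } else {
      s1 <- end(genes)[i] + 1L
      e1 <- end(genes)[i] + upstream
      anchor <- s1
    }
    if (e1 < 1L || s1 > e1) next
    win <- GRanges(seqnames(genes)[i], IRanges(max(1L, s1), e1))
    keep <- GenomicRanges::setdiff(win, cds, ignore.strand = TRUE)
    if (length(keep) == 0L) next
    # keep only the piece touching the TSS-proximal boundary
    prox <- keep[start(keep) <= anchor & end(keep) >= anchor]
    if (length(prox)) parts[[i]] <- prox
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L)
    return(.applyGenome(GRanges(), seqinfo(genes)))
  out <- do.call(c, parts)
  out <- .applyGenome(out, seqinfo(genes))
  mergeIntervals(out)
}

#' TSS distance summary of motif sites
#'
#' Per site, the signed distance from the site midpoint to the nearest TSS
#' (negative upstream of the gene in the gene's own orientation). Sites are
#' split by any-overlap with annotated repeats; medians are reported per
#' split, together with the percentage of sites in repeats.
#'
#' @param sites a [MotifSiteSet] (or `GRanges`).
#' @param gm a [GeneModelSet].
#' @param repeats `GRanges` of repeat intervals.
#' @return a list with `medianNR`, `medianIR` (bp, `NA` when a split is
#'   empty), `pctInRepeats` (0-100) and the per-site `distance` vector.
#' @export
tssDistanceSummary <- function(sites, gm, repeats = GRanges()) {
  gr <- if (is(sites, "MotifSiteSet")) siteRanges(sites) else sites
  if (length(geneBodies(gm)) == 0L) stop("no genes supplied")
  if (length(gr) == 0L) stop("no sites supplied")
  tss <- tssSites(gm)
  mids <- fragmentMidpoints(granges(gr))
  idx <- nearest(mids, tss, ignore.strand = TRUE)
  tssStd <- as.character(strand(tss))[idx]
  d <- start(mids) - start(tss)[idx]
  d <- ifelse(tssStd == "-", -d, d)
  inRep <- overlapsAny(gr, repeats, ignore.strand = TRUE)
  list(medianNR = if (any(!inRep)) median(d[!inRep]) else NA_real_,
       medianIR = if (any(inRep)) median(d[inRep]) else NA_real_,
       pctInRepeats = 100 * mean(inRep),
       distance = d)
}

#' Merge motif sites of many models into contigs
#'
#' Strand-collapsed union of all site intervals (gap 0), the
#' "merged motif regions" summary.
#'
#' @param siteSets a list of [MotifSiteSet]s (or a single one).
#' @return a list with `contigs` (merged `GRanges`) and `meanWidth` (bp).
#' @export
mergeMotifSites <- function(siteSets) {
  if (is(siteSets, "MotifSiteSet")) siteSets <- list(siteSets)
  grs <- lapply(siteSets, function(s) granges(siteRanges(s)))
  all <- do.call(c, grs)
  contigs <- mergeIntervals(all, gap = 0L)
  list(contigs = contigs,
       meanWidth = if (length(contigs)) mean(width(contigs)) else NA_real_)
}

# Mean oriented local track profile around site midpoints (+/- halfWindow).
.localCoverage <- function(track, gr, halfWindow) {
  if (length(gr) == 0L) return(rep(NA_real_, 2L * halfWindow + 1L))
  mids <- fragmentMidpoints(granges(gr))
  total <- numeric(2L * halfWindow + 1L)
  count <- numeric(2L * halfWindow + 1L)
  chs <- as.character(seqnames(mids))
  m0 <- start(mids) - 1L
  for (i in seq_along(mids)) {
    pos <- (m0[i] - halfWindow):(m0[i] + halfWindow)
    v <- .trackValueAt(track, chs[i], pos)
    ok <- !is.na(v)
    total[ok] <- total[ok] + v[ok]
    count <- count + ok
  }
  prof <- total / count
  prof[count == 0] <- NA_real_
  prof
}

#' Build a per-motif catalog
#'
#' One page per motif model: site count, percentage of sites in repeats,
#' median TSS distance with a positional histogram (+/- 2 kb of the TSS),
#' local base composition (+/- 20 bp of site midpoints) and mean local track
#' coverage (+/- 250 bp), each split into All / NR (not in repeats) / IR (in
#' repeats). Splits without sites are flagged as empty.
#'
#' @param models list of [MotifModel]s.
#' @param siteSets list of matching [MotifSiteSet]s (same order).
#' @param gm a [GeneModelSet].
#' @param repeats `GRanges` of repeats.
#' @param track a [CoverageTrack] for the local-coverage panel.
#' @param sequences the genome `DNAStringSet` for base composition.
#' @return a list of per-motif page lists (class `"moaCatalog"`).
#' @export
buildCatalog <- function(models, siteSets, gm, repeats, track, sequences) {
  stopifnot(length(models) == length(siteSets))
  histBreaks <- seq(-2000L, 2000L, by = 100L)
  pages <- lapply(seq_along(models), function(i) {
    model <- models[[i]]
    gr <- siteRanges(siteSets[[i]])
    inRep <- if (length(gr)) overlapsAny(gr, repeats, ignore.strand = TRUE)
             else logical(0)
    tssAll <- if (length(gr))
      tssDistanceSummary(siteSets[[i]], gm, repeats) else
      list(medianNR = NA_real_, medianIR = NA_real_, pctInRepeats = NA_real_,
           distance = numeric(0))
    d <- tssAll$distance
    splitProf <- function(sel) {
      sub <- gr[sel]
      list(n = length(sub),
           empty = length(sub) == 0L,
           medianTss = if (length(sub)) median(d[sel]) else NA_real_,
           tssHist = {
             dd <- d[sel]
             dd <- dd[dd >= -2000 & dd < 2000]
             as.integer(table(cut(dd, breaks = histBreaks, right = FALSE)))
           },
           baseComposition = .baseComposition(sequences, sub, 20L),
           localCoverage = .localCoverage(track, sub, 250L))
    }
    list(name = model@name, kind = model@kind,
         consensus = .consensusLabel(model,
           if (model@kind == "dyad") model@spacerMin else NULL),
         nSites = length(gr),
         pctInRepeats = if (length(gr)) 100 * mean(inRep) else NA_real_,
         all = splitProf(rep(TRUE, length(gr))),
         nr = splitProf(!inRep),
         ir = splitProf(inRep))
  })
  names(pages) <- vapply(models, function(m) m@name, character(1))
  class(pages) <- "moaCatalog"
  pages
}

# A/C/G/T counts in +/- halfWindow of site midpoints.
.baseComposition <- function(sequences, gr, halfWindow) {
  if (length(gr) == 0L)
    return(setNames(integer(4), c("A", "C", "G", "T")))
  mids <- fragmentMidpoints(granges(gr))
  counts <- setNames(numeric(4), c("A", "C", "G", "T"))
  chs <- as.character(seqnames(mids))
  for (i in seq_along(mids)) {
    L <- length(sequences[[chs[i]]])
    s <- max(1L, start(mids)[i] - halfWindow)
    e <- min(L, start(mids)[i] + halfWindow)
    f <- alphabetFrequency(subseq(sequences[[chs[i]]], s, e),
                           baseOnly = TRUE)
    counts <- counts + f[c("A", "C", "G", "T")]
  }
  counts
}

#' Write a catalog as one-page-per-motif text
#'
#' @param catalog result of [buildCatalog()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCatalog <- function(catalog, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (page in catalog) {
    writeLines(c(strrep("=", 70),
      sprintf("Motif %s (%s)  consensus: %s", page$name, page$kind,
              page$consensus),
      sprintf("Total sites: %d    in repeats: %s%%", page$nSites,
              format(round(page$pctInRepeats, 1))),
      ""), con)
    for (nm in c("all", "nr", "ir")) {
      sp <- page[[nm]]
      hdr <- c(all = "All sites", nr = "NR (not in repeats)",
               ir = "IR (in repeats)")[[nm]]
      if (sp$empty) {
        writeLines(sprintf("[%s] empty split", hdr), con)
        next
      }
      writeLines(c(
        sprintf("[%s] n = %d, median TSS distance = %s bp", hdr, sp$n,
                format(sp$medianTss)),
        sprintf("  base composition (+/-20 bp): A=%d C=%d G=%d T=%d",
                sp$baseComposition[["A"]], sp$baseComposition[["C"]],
                sp$baseComposition[["G"]], sp$baseComposition[["T"]]),
        sprintf("  mean local coverage (+/-250 bp): %s",
                format(signif(mean(sp$localCoverage, na.rm = TRUE), 4))),
        sprintf("  TSS histogram (100 bp bins, -2kb..2kb): %s",
                paste(sp$tssHist, collapse = ","))), con)
    }
    writeLines("", con)
  }
  invisible(file)
}
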