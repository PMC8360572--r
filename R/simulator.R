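# Synthetic chromatin template, MNase partial-digest fragment generator and
# truth-based evaluation. The template encodes the two particle classes of
# the assay - nucleosome cores (147 bp) and small protein-bound sites
# (10-25 bp) - so the full pipeline can be exercised without external data.

#' Template parameters for the chromatin simulator
#'
#' Defaults describe a compact but realistic plant-like test genome: two
#' 500 kb chromosomes, 100 genes with a 350 bp nucleosome-free region (NFR)
#' upstream of each TSS, 200 protein-bound (TF) sites of 10-25 bp (one per
#' promoter, the rest as intergenic enhancers), nucleosomes tiled at 147 bp
#' cores + 30 bp linkers outside NFRs, and a handful of multi-kb repeats.
#' Promoter-site occupancy is a monotone increasing function of the host
#' gene's expression (rank-mapped into `piRange`).
#'
#' @param nChroms,chromLength genome shape.
#' @param nGenes,geneLengthRange gene count and body length range (bp).
#' @param nTfSites,tfWidthRange TF-site count and width range (bp).
#' @param piRange occupancy probability range; promoter sites are rank-mapped
#'   into it by expression, enhancer sites drawn uniformly from it.
#' @param motifs list of [MotifModel]s planted at site centers (cycled).
#' @param nfrWidth nucleosome-free region upstream of each TSS (bp).
#' @param nucleosomeWidth,linkerWidth,nucleosomeOccupancy,jitterSd nucleosome
#'   core geometry, per-molecule occupancy and positional jitter SD (bp).
#' @param nRepeats,repeatWidthRange repeat annotation per chromosome.
#' @param gc genome GC content.
#' @param exprMeanlog,exprSdlog log-normal expression parameters.
#' @return a named list of class `"moaTemplateParams"`.
#' @export
templateParams <- function(nChroms = 2L, chromLength = 500000L,
                           nGenes = 100L, geneLengthRange = c(1000L, 3000L),
                           nTfSites = 200L, tfWidthRange = c(10L, 25L),
                           piRange = c(0.1, 0.95),
                           motifs = list(motifModel("om001", "oligo",
                                                    "ACGTCA")),
                           nfrWidth = 350L, nucleosomeWidth = 147L,
                           linkerWidth = 30L, nucleosomeOccupancy = 0.9,
                           jitterSd = 10, nRepeats = 6L,
                           repeatWidthRange = c(2000L, 8000L), gc = 0.5,
                           exprMeanlog = 2, exprSdlog = 1) {
  p <- as.list(environment())
  stopifnot(p$nChroms >= 1L, p$chromLength > 0L, p$nGenes >= 1L,
            p$nTfSites >= 0L, all(p$piRange >= 0 & p$piRange <= 1),
            p$tfWidthRange[1] >= 6L)
  class(p) <- "moaTemplateParams"
  p
}

#' Digestion parameters
#'
#' @param cutRate cuts per unprotected bp per molecule, i.e. the reciprocal
#'   of the mean naked-DNA fragment length (default 1/10). The digest is
#'   deliberately heavy relative to the 30 bp size-selection floor: with no
#'   explicit exonuclease step, shredding unprotected DNA below the retained
#'   size range is what makes size selection stand in for
#'   trimming-to-footprint, so that retained small fragments are
#'   predominantly particle-protected.
#' @param nMolecules genome copies digested (default 250).
#' @param sizeRange retained fragment length range in bp after the
#'   size-selection step (default 30-80, the small-fragment class).
#' @param protectionCompleteness probability that a bound particle actually
#'   blocks cutting in a given molecule (default 0.95).
#' @param controlAtBias multiplicative cut-rate factor at A/T bases in the
#'   naked-DNA control (default 1 = unbiased).
#' @param depth optional cap: subsample the pooled fragments to this many.
#' @return a named list of class `"moaDigestParams"`.
#' @export
digestParams <- function(cutRate = 1 / 10, nMolecules = 250L,
                         sizeRange = c(30L, 80L),
                         protectionCompleteness = 0.95, controlAtBias = 1,
                         depth = NULL) {
  p <- as.list(environment())
  stopifnot(p$cutRate > 0, p$sizeRange[1] < p$sizeRange[2],
            p$nMolecules >= 1L)
  class(p) <- "moaDigestParams"
  p
}

# Realize an IUPAC consensus into a concrete sequence (one random base per
# ambiguity code).
.realizeConsensus <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(letters, function(ch) {
    opts <- strsplit(IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

.plantPattern <- function(model) {
  if (model@kind == "oligo") return(.realizeConsensus(model@consensus))
  s <- if (model@spacerMin == model@spacerMax) model@spacerMin
       else sample(model@spacerMin:model@spacerMax, 1L)
  paste0(.realizeConsensus(model@leftWord),
         paste(sample(c("A", "C", "G", "T"), s, replace = TRUE),
               collapse = ""),
         .realizeConsensus(model@rightWord))
}

#' Build a synthetic chromatin template
#'
#' Deterministic given `seed`. Genes are placed in evenly spaced slots with a
#' nucleosome-free region upstream of each TSS; one TF site is planted in
#' each promoter NFR (occupancy rank-mapped from the gene's expression into
#' `piRange`) and the remaining sites become intergenic enhancers in their
#' own accessible pockets. Every TF site carries an exact match to its motif
#' consensus at its center (random strand).
#'
#' @param params a [templateParams()] list.
#' @param seed integer random seed.
#' @return a [ChromatinTemplate].
#' @export
buildTemplate <- function(params = templateParams(), seed = 1L) {
  set.seed(seed)
  p <- params
  L <- as.integer(p$chromLength)
  chroms <- paste0("chr", seq_len(p$nChroms))
  sinfo <- Seqinfo(chroms, rep(L, p$nChroms))
  baseProb <- c(A = (1 - p$gc) / 2, C = p$gc / 2, G = p$gc / 2,
                T = (1 - p$gc) / 2)
  genesPer <- diff(round(seq(0, p$nGenes, length.out = p$nChroms + 1L)))
  nProm <- min(p$nGenes, p$nTfSites)
  nEnh <- p$nTfSites - nProm
  enhPer <- diff(round(seq(0, nEnh, length.out = p$nChroms + 1L)))

  seqChars <- list()
  geneRows <- list(); cdsRows <- list(); siteRows <- list()
  nucRows <- list(); repRows <- list()
  geneIdx <- 0L
  margin <- p$nfrWidth + 600L

  for (ci in seq_len(p$nChroms)) {
    ch <- chroms[ci]
    sq <- sample(names(baseProb), L, replace = TRUE, prob = baseProb)
    nG <- genesPer[ci]
    slotLen <- L %/% nG
    if (slotLen < max(p$geneLengthRange) + 2L * margin)
      stop("infeasible packing: genes do not fit the chromosome")
    gstart <- integer(nG); gend <- integer(nG); gstrand <- character(nG)
    for (g in seq_len(nG)) {
      glen <- sample(p$geneLengthRange[1]:p$geneLengthRange[2], 1L)
      off <- sample(margin:(slotLen - glen - margin), 1L)
      gstart[g] <- (g - 1L) * slotLen + off + 1L   # 1-based
      gend[g] <- gstart[g] + glen - 1L
      gstrand[g] <- sample(c("+", "-"), 1L)
    }
    ids <- sprintf("gene%04d", geneIdx + seq_len(nG))
    geneIdx <- geneIdx + nG
    geneRows[[ci]] <- data.frame(chrom = ch, start = gstart, end = gend,
                                 strand = gstrand, id = ids)
    trim <- pmax(1L, as.integer(round(0.15 * (gend - gstart + 1L))))
    cdsRows[[ci]] <- data.frame(chrom = ch, start = gstart + trim,
                                end = gend - trim, gene_id = ids)
    seqChars[[ch]] <- sq
  }

  genesDf <- do.call(rbind, geneRows)
  expr <- rlnorm(nrow(genesDf), meanlog = p$exprMeanlog, sdlog = p$exprSdlog)
  names(expr) <- genesDf$id
  # promoter-site occupancy: monotone in expression (global rank map)
  rk <- rank(expr, ties.method = "first")
  piProm <- p$piRange[1] +
    (p$piRange[2] - p$piRange[1]) * (rk - 1) / max(1L, length(rk) - 1L)

  promGenes <- if (nProm < nrow(genesDf))
    sort(sample(nrow(genesDf), nProm)) else seq_len(nrow(genesDf))

  nfrList <- list()   # per-chrom exclusion zones for nucleosome tiling
  motifCycle <- function(i) p$motifs[[((i - 1L) %% length(p$motifs)) + 1L]]
  siteCount <- 0L

  addSite <- function(ch, center0, width, pi, class, model) {
    s0 <- center0 - (width - 1L) %/% 2L
    e0 <- s0 + width            # half-open end
    pat <- .plantPattern(model)
    k <- nchar(pat)
    ins <- if (runif(1) < 0.5) pat else
      as.character(reverseComplement(DNAString(pat)))
    m0 <- center0 - (k - 1L) %/% 2L
    seqChars[[ch]][(m0 + 1L):(m0 + k)] <<- strsplit(ins, "")[[1]]
    data.frame(chrom = ch, start0 = s0, end0 = e0, occupancy = pi,
               class = class, motif = model@name,
               consensus = if (model@kind == "oligo") model@consensus
                           else paste0(model@leftWord, "+", model@rightWord),
               center0 = center0)
  }

  # promoter sites
  for (j in seq_along(promGenes)) {
    i <- promGenes[j]
    ch <- genesDf$chrom[i]
    tss0 <- if (genesDf$strand[i] == "+") genesDf$start[i] - 1L
            else genesDf$end[i] - 1L
    dUp <- sample(80L:(p$nfrWidth - 60L), 1L)
    center0 <- if (genesDf$strand[i] == "+") tss0 - dUp else tss0 + dUp
    w <- sample(p$tfWidthRange[1]:p$tfWidthRange[2], 1L)
    siteCount <- siteCount + 1L
    siteRows[[siteCount]] <- addSite(ch, center0, w, piProm[i], "promoter",
                                     motifCycle(siteCount))
  }

  # per-chrom gene exclusion (gene body + NFR + margin) for enhancer/repeat
  # placement
  geneZone <- GRanges(genesDf$chrom,
                      IRanges(pmax(1L, genesDf$start - p$nfrWidth - 200L),
                              pmin(L, genesDf$end + p$nfrWidth + 200L)))

  enhPockets <- list()
  for (ci in seq_len(p$nChroms)) {
    ch <- chroms[ci]
    placed <- GRanges()
    nPlaced <- 0L
    tries <- 0L
    while (nPlaced < enhPer[ci] && tries < 50L * max(1L, enhPer[ci])) {
      tries <- tries + 1L
      w <- sample(p$tfWidthRange[1]:p$tfWidthRange[2], 1L)
      center0 <- sample(500L:(L - 500L), 1L)
      cand <- GRanges(ch, IRanges(center0 - 100L, center0 + 100L))
      if (any(overlapsAny(cand, geneZone)) || overlapsAny(cand, placed))
        next
      placed <- c(placed, cand)
      nPlaced <- nPlaced + 1L
      siteCount <- siteCount + 1L
      siteRows[[siteCount]] <- addSite(ch, center0, w,
        runif(1, p$piRange[1], p$piRange[2]), "intergenic_enhancer",
        motifCycle(siteCount))
    }
    if (nPlaced < enhPer[ci])
      stop("infeasible packing: could not place enhancer sites")
    enhPockets[[ch]] <- placed
  }

  sitesDf <- do.call(rbind, siteRows)

  # nucleosome tiling outside NFRs and enhancer pockets
  for (ci in seq_len(p$nChroms)) {
    ch <- chroms[ci]
    period <- p$nucleosomeWidth + p$linkerWidth
    phase <- sample(0:(period - 1L), 1L)
    starts0 <- seq.int(phase, L - p$nucleosomeWidth, by = period)
    cores <- GRanges(ch, IRanges(starts0 + 1L,
                                 width = p$nucleosomeWidth))
    gd <- genesDf[genesDf$chrom == ch, ]
    nfr <- GRanges(ch, IRanges(
      ifelse(gd$strand == "+", pmax(1L, gd$start - p$nfrWidth), gd$end + 1L),
      ifelse(gd$strand == "+", gd$start - 1L,
             pmin(L, gd$end + p$nfrWidth))))
    excl <- c(nfr, enhPockets[[ch]])
    cores <- cores[!overlapsAny(cores, excl)]
    nucRows[[ci]] <- data.frame(chrom = ch, start = start(cores),
                                end = end(cores))
  }

  # repeats: intergenic intervals; the first one per chromosome is anchored
  # over an enhancer pocket (when present) so repeat splits are exercised
  for (ci in seq_len(p$nChroms)) {
    ch <- chroms[ci]
    reps <- list()
    pockets <- enhPockets[[ch]]
    nWanted <- p$nRepeats
    if (length(pockets) > 0L && nWanted > 0L) {
      c0 <- start(pockets)[1L] + 100L
      w <- sample(p$repeatWidthRange[1]:p$repeatWidthRange[2], 1L)
      reps[[1L]] <- c(max(1L, c0 - w %/% 2L), min(L, c0 + w %/% 2L))
    }
    tries <- 0L
    while (length(reps) < nWanted && tries < 200L) {
      tries <- tries + 1L
      w <- sample(p$repeatWidthRange[1]:p$repeatWidthRange[2], 1L)
      s1 <- sample(1L:(L - w), 1L)
      cand <- GRanges(ch, IRanges(s1, s1 + w - 1L))
      if (any(overlapsAny(cand, geneZone))) next
      reps[[length(reps) + 1L]] <- c(s1, s1 + w - 1L)
    }
    if (length(reps))
      repRows[[ci]] <- data.frame(chrom = ch,
                                  start = vapply(reps, `[`, 0L, 1L),
                                  end = vapply(reps, `[`, 0L, 2L))
  }

  sequences <- DNAStringSet(vapply(seqChars, paste, character(1),
                                   collapse = ""))
  names(sequences) <- chroms

  genes <- GRanges(genesDf$chrom, IRanges(genesDf$start, genesDf$end),
                   strand = genesDf$strand, seqinfo = sinfo)
  names(genes) <- genesDf$id
  cdsDf <- do.call(rbind, cdsRows)
  cds <- GRanges(cdsDf$chrom, IRanges(cdsDf$start, cdsDf$end),
                 seqinfo = sinfo)
  mcols(cds)$gene_id <- cdsDf$gene_id
  gm <- geneModelSet(genes, cds)

  tf <- GRanges(sitesDf$chrom, IRanges(sitesDf$start0 + 1L, sitesDf$end0),
                seqinfo = sinfo)
  mcols(tf)$occupancy <- sitesDf$occupancy
  mcols(tf)$class <- sitesDf$class
  mcols(tf)$motif <- sitesDf$motif
  mcols(tf)$consensus <- sitesDf$consensus

  nucDf <- do.call(rbind, nucRows)
  nuc <- GRanges(nucDf$chrom, IRanges(nucDf$start, nucDf$end),
                 seqinfo = sinfo)
  mcols(nuc)$occupancy <- p$nucleosomeOccupancy
  mcols(nuc)$jitterSd <- p$jitterSd

  repDf <- if (length(repRows)) do.call(rbind, repRows) else NULL
  reps <- if (is.null(repDf)) GRanges(seqinfo = sinfo)
          else GRanges(repDf$chrom, IRanges(repDf$start, repDf$end),
                       seqinfo = sinfo)

  new("ChromatinTemplate", sequences = sequences, geneModels = gm,
      expression = expr, nucleosomes = nuc, tfSites = tf, repeats = reps)
}

# Digest one chromosome of one molecule: returns 0-based cut positions ->
# fragment start/end vectors (already size-filtered).
.digestMolecule <- function(L, prot, cutRate, sizeRange) {
  unprot <- if (length(prot) == 0L) IRanges(1L, L)
            else IRanges::gaps(reduce(prot), start = 1L, end = L)
  w <- width(unprot)
  U <- sum(as.numeric(w))
  if (U <= 0) return(NULL)
  K <- rpois(1L, cutRate * U)
  if (K == 0L) return(NULL)
  u <- sort(runif(K) * U)
  b0 <- c(0, cumsum(as.numeric(w)))
  idx <- findInterval(u, b0)
  idx[idx > length(w)] <- length(w)
  cut0 <- floor(start(unprot)[idx] - 1 + (u - b0[idx]))
  cuts <- unique(c(0, cut0, L))
  fs <- cuts[-length(cuts)]
  fe <- cuts[-1L]
  len <- fe - fs
  keep <- len >= sizeRange[1] & len <= sizeRange[2]
  if (!any(keep)) return(NULL)
  cbind(fs[keep], fe[keep])
}

.poolFragments <- function(rows, chroms, sinfo, libraryId, depth, seed) {
  withFrags <- names(rows)[lengths(rows) > 0L]
  if (length(withFrags) == 0L) stop("digestion retained zero fragments")
  grs <- lapply(withFrags, function(ch) {
    m <- do.call(rbind, rows[[ch]])
    GRanges(ch, IRanges(m[, 1L] + 1L, m[, 2L]), seqinfo = sinfo)
  })
  gr <- do.call(c, grs)
  if (!is.null(depth) && length(gr) > depth)
    gr <- gr[sort(sample(length(gr), depth))]
  fragmentSet(gr, libraryId)
}

#' Simulate an MNase partial digest of chromatin
#'
#' Per molecule, each nucleosome core and TF site is independently occupied
#' (Bernoulli: `occupancy * protectionCompleteness`); nucleosome positions
#' are jittered (`N(0, jitterSd)`). Cut positions follow a Poisson process of
#' rate `cutRate` on unprotected bases (zero on protected bases); fragments
#' are the intervals between consecutive cuts, retained when their length
#' falls in `sizeRange`, pooled over molecules and optionally subsampled to
#' `depth`.
#'
#' @param tpl a [ChromatinTemplate].
#' @param dp a [digestParams()] list.
#' @param seed integer random seed (identical seeds give identical output).
#' @return a [FragmentSet].
#' @export
simulateDigest <- function(tpl, dp = digestParams(), seed = 1L) {
  set.seed(seed)
  sinfo <- genomeOf(tpl@sequences)
  chroms <- names(tpl@sequences)
  rows <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    L <- Biostrings::width(tpl@sequences)[[match(ch, names(tpl@sequences))]]
    nuc <- tpl@nucleosomes[seqnames(tpl@nucleosomes) == ch]
    sites <- tpl@tfSites[seqnames(tpl@tfSites) == ch]
    ns0 <- start(nuc); nOcc <- mcols(nuc)$occupancy
    jSd <- if (length(nuc)) mcols(nuc)$jitterSd else numeric(0)
    nw <- width(nuc)
    pi <- mcols(sites)$occupancy
    acc <- vector("list", dp$nMolecules)
    for (m in seq_len(dp$nMolecules)) {
      keepN <- runif(length(nuc)) < nOcc * dp$protectionCompleteness
      protN <- if (any(keepN)) {
        js <- pmin(pmax(ns0[keepN] +
                          as.integer(round(rnorm(sum(keepN), 0, jSd[keepN]))),
                        1L), L - nw[keepN] + 1L)
        IRanges(js, width = nw[keepN])
      } else IRanges()
      keepS <- runif(length(sites)) < pi * dp$protectionCompleteness
      protS <- if (any(keepS))
        IRanges(start(sites)[keepS], end(sites)[keepS]) else IRanges()
      frag <- .digestMolecule(L, c(protN, protS), dp$cutRate, dp$sizeRange)
      if (!is.null(frag)) acc[[m]] <- frag
    }
    rows[[ch]] <- acc[!vapply(acc, is.null, logical(1))]
  }
  .poolFragments(rows, chroms, sinfo,
                 sprintf("moa_digest_seed%d", seed), dp$depth, seed)
}

#' Simulate the naked-DNA digestion control
#'
#' As [simulateDigest()] but with no protected intervals; `controlAtBias`
#' multiplies the per-base cut rate at A/T bases to emulate nuclease
#' sequence preference.
#'
#' @inheritParams simulateDigest
#' @return a [FragmentSet].
#' @export
simulateControl <- function(tpl, dp = digestParams(), seed = 1L) {
  set.seed(seed)
  sinfo <- genomeOf(tpl@sequences)
  chroms <- names(tpl@sequences)
  rows <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    L <- Biostrings::width(tpl@sequences)[[match(ch, names(tpl@sequences))]]
    biased <- dp$controlAtBias != 1
    if (biased) {
      at <- as.integer(strsplit(as.character(tpl@sequences[[ch]]),
                                "")[[1]] %in% c("A", "T"))
      wts <- ifelse(at == 1L, dp$controlAtBias, 1)
      cw <- cumsum(wts)
      total <- cw[L]
    }
    acc <- vector("list", dp$nMolecules)
    for (m in seq_len(dp$nMolecules)) {
      if (biased) {
        K <- rpois(1L, dp$cutRate * total)
        if (K == 0L) next
        u <- runif(K) * total
        cut0 <- findInterval(u, c(0, cw))
        cut0 <- pmin(cut0, L - 1L)
      } else {
        K <- rpois(1L, dp$cutRate * L)
        if (K == 0L) next
        cut0 <- floor(runif(K) * L)
      }
      cuts <- unique(sort(c(0, cut0, L)))
      fs <- cuts[-length(cuts)]
      fe <- cuts[-1L]
      len <- fe - fs
      keep <- len >= dp$sizeRange[1] & len <= dp$sizeRange[2]
      if (any(keep)) acc[[m]] <- cbind(fs[keep], fe[keep])
    }
    rows[[ch]] <- acc[!vapply(acc, is.null, logical(1))]
  }
  .poolFragments(rows, chroms, sinfo,
                 sprintf("control_digest_seed%d", seed), dp$depth, seed)
}

#' Score called peaks against the planted truth
#'
#' A truth site is recovered iff some peak midpoint lies within `tol` bp of
#' its center; precision is the fraction of peaks whose midpoint lies within
#' `tol` bp of any truth center. The per-peak center error is the distance
#' from the peak midpoint to the nearest truth center; the median is taken
#' over all called peaks.
#'
#' @param peaks a [SegmentSet] or merged `GRanges`.
#' @param truth `GRanges` of truth sites (non-empty).
#' @param tol tolerance in bp (default 10).
#' @return a list with `recall`, `precision`, `medianCenterError`.
#' @export
evaluateTruth <- function(peaks, truth, tol = 10L) {
  gr <- if (is(peaks, "SegmentSet")) peakRanges(peaks) else peaks
  if (length(truth) == 0L) stop("empty truth set")
  if (length(gr) == 0L)
    return(list(recall = 0, precision = NA_real_,
                medianCenterError = NA_real_))
  pm <- start(fragmentMidpoints(granges(gr))) - 1L
  tc <- start(fragmentMidpoints(granges(truth))) - 1L
  pch <- as.character(seqnames(gr))
  tch <- as.character(seqnames(truth))
  errPeak <- vapply(seq_along(pm), function(i) {
    same <- which(tch == pch[i])
    if (length(same) == 0L) return(Inf)
    min(abs(tc[same] - pm[i]))
  }, numeric(1))
  errTruth <- vapply(seq_along(tc), function(i) {
    same <- which(pch == tch[i])
    if (length(same) == 0L) return(Inf)
    min(abs(pm[same] - tc[i]))
  }, numeric(1))
  list(recall = mean(errTruth <= tol),
       precision = mean(errPeak <= tol),
       medianCenterError = median(errPeak[is.finite(errPeak)]))
}

#' Write a template to disk
#'
#' Emits the genome FASTA, gene models as GFF3, truth BEDs (TF sites with
#' occupancy in the score column; nucleosomes; repeats) and the expression
#' TSV.
#'
#' @param tpl a [ChromatinTemplate].
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
writeTemplate <- function(tpl, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  writeXStringSet(tpl@sequences, fa)
  gm <- tpl@geneModels
  genes <- geneBodies(gm)
  g <- granges(genes)
  mcols(g)$type <- "gene"
  mcols(g)$ID <- names(genes)
  mcols(g)$Parent <- IRanges::CharacterList(
    rep(list(character(0)), length(g)))
  cd <- granges(cdsParts(gm))
  mcols(cd)$type <- "CDS"
  mcols(cd)$ID <- paste0("cds_", seq_along(cd))
  mcols(cd)$Parent <- IRanges::CharacterList(
    as.list(mcols(cdsParts(gm))$gene_id))
  gff <- c(g, cd)
  mcols(gff)$source <- "moaseq_simulator"
  gffFile <- file.path(dir, "genes.gff3")
  # CDS phase is not modeled; rtracklayer warns about the missing field
  suppressWarnings(rtracklayer::export(gff, gffFile, format = "gff3"))
  tfFile <- file.path(dir, "tf_sites.bed")
  tf <- granges(tpl@tfSites)
  if (length(tf)) {
    names(tf) <- paste0(mcols(tpl@tfSites)$motif, "_site", seq_along(tf))
    mcols(tf)$score <- mcols(tpl@tfSites)$occupancy
  }
  writeBed(tf, tfFile)
  nucFile <- file.path(dir, "nucleosomes.bed")
  writeBed(granges(tpl@nucleosomes), nucFile)
  repFile <- file.path(dir, "repeats.bed")
  writeBed(granges(tpl@repeats), repFile)
  exFile <- file.path(dir, "expression.tsv")
  write.table(data.frame(gene_id = names(tpl@expression),
                         expression = unname(tpl@expression)),
              exFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gffFile, tfSites = tfFile,
              nucleosomes = nucFile, repeats = repFile,
              expression = exFile))
}
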