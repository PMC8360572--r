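# Shared fixtures. All test intervals are written in 0-based half-open (BED)
# coordinates via gr0() so the expectations can be read directly against the
# BED convention.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(GenomeInfoDb)
  library(Biostrings)
  library(S4Vectors)
})

tinyGenome <- function(lengths = c(chr1 = 1000L)) {
  Seqinfo(seqnames = names(lengths), seqlengths = unname(lengths))
}

# GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, strand = "*", genome = NULL,
                names = NULL) {
  g <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(genome)) g <- GRanges(seqnames(g), ranges(g),
                                     strand = strand(g), seqinfo = genome)
  if (!is.null(names)) names(g) <- names
  g
}

# 0-based half-open view of a GRanges, for direct comparison
bed0 <- function(g) {
  data.frame(chrom = as.character(seqnames(g)), start = start(g) - 1L,
             end = end(g))
}

fset <- function(chrom, start0, end0, genome = NULL, id = "test") {
  fragmentSet(gr0(chrom, start0, end0, genome = genome), libraryId = id)
}

# Bare track from explicit per-chromosome value vectors
makeTrack <- function(values, step = 10L, binWidth = step, kind = "coverage",
                      normalization = "raw", nFragments = NA_real_) {
  lens <- vapply(values, length, integer(1)) * step
  genome <- Seqinfo(names(values), unname(lens))
  moaseq:::.newTrack(genome, binWidth, step, values, normalization, kind,
                     nFragments)
}

makeStats <- function(mean = 0, sd = 1, mad = sd) {
  new("ScaleStats", mean = mean, sd = sd, mad = mad,
      support = SimpleList())
}

# Minimal gene model fixture: genes as (chrom, start0, end0, strand, id),
# cds as fraction-trimmed bodies unless given explicitly
makeGenes <- function(chrom, start0, end0, strand, ids, genome = NULL,
                      cdsStart0 = NULL, cdsEnd0 = NULL) {
  genes <- gr0(chrom, start0, end0, strand, genome, names = ids)
  if (is.null(cdsStart0)) {
    cds <- GRanges()
    mcols(cds)$gene_id <- character(0)
  } else {
    cds <- gr0(chrom, cdsStart0, cdsEnd0, genome = genome)
    mcols(cds)$gene_id <- ids
  }
  geneModelSet(genes, cds)
}

# Small simulation preset used across simulator tests (fast, single chrom)
smallTemplateParams <- function(...) {
  templateParams(nChroms = 1L, chromLength = 60000L, nGenes = 6L,
                 nTfSites = 12L, nRepeats = 2L,
                 repeatWidthRange = c(500L, 1500L), ...)
}

smallDigestParams <- function(...) {
  digestParams(nMolecules = 40L, ...)
}
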