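# Coordinate conventions, interval arithmetic and readers/writers for the
# standard formats every other module touches.
#
# All coordinates are BED-convention 0-based half-open at file boundaries and
# GRanges 1-based closed internally; 1-based formats (GFF3) are converted at
# the boundary by rtracklayer.

#' Read a chromosome-size table
#'
#' Two-column TSV (chromosome name, length in bp), no header.
#'
#' @param file path to the table.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(file) {
  tab <- read.table(file, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  if (anyDuplicated(tab$chrom)) stop("duplicate chromosome names")
  if (any(tab$length <= 0L)) stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = tab$chrom, seqlengths = tab$length)
}

#' Construct a genome table from names and lengths
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of lengths (> 0).
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
genomeTable <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  Seqinfo(seqnames = as.character(chrom), seqlengths = as.integer(length))
}

# Attach a Seqinfo to a GRanges, clipping out-of-bounds intervals with a
# warning (tolerates off-by-one inputs) and erroring on unknown chromosomes.
.applyGenome <- function(gr, genome) {
  if (is.null(genome)) return(gr)
  unknown <- setdiff(as.character(unique(seqnames(gr))), seqlevels(genome))
  if (length(unknown))
    stop("chromosome(s) not in genome table: ", paste(unknown, collapse = ", "))
  gr2 <- suppressWarnings(GRanges(seqnames(gr), IRanges::ranges(gr),
                                  strand = strand(gr), seqinfo = genome))
  mcols(gr2) <- mcols(gr)
  names(gr2) <- names(gr)
  lens <- seqlengths(genome)[as.character(seqnames(gr2))]
  oob <- start(gr2) < 1L | end(gr2) > lens
  if (any(oob)) {
    warning(sum(oob), " interval(s) clipped to chromosome bounds")
    gr2 <- suppressWarnings(GenomicRanges::trim(gr2))
    gr2 <- gr2[width(gr2) > 0L]
  }
  gr2
}

#' Read a BED file (BED3/BED6) as GRanges
#'
#' Tab-separated, no header. Coordinates are converted from 0-based half-open
#' to 1-based closed. Intervals beyond chromosome bounds are clipped with a
#' warning when a genome table is supplied.
#'
#' @param file path to the BED file.
#' @param genome optional [GenomeInfoDb::Seqinfo]; enables bounds checking.
#' @return a `GRanges`, with `name` as names and `score` metadata when present.
#' @export
readBed <- function(file, genome = NULL) {
  gr <- rtracklayer::import(file, format = "BED")
  .applyGenome(gr, genome)
}

#' Write a GRanges as BED
#'
#' BED3 when the ranges carry neither names nor scores, BED6 otherwise.
#'
#' @param gr a `GRanges`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeBed <- function(gr, file) {
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Merge intervals, closing gaps up to `gap` bp
#'
#' Overlapping intervals and intervals separated by at most `gap` bp are
#' merged into contiguous intervals (strand is ignored). With `gap = 1` this
#' is the final-peak rule: adjacent book-ended peaks or those separated by
#' 1 bp are merged. Idempotent.
#'
#' @param x a `GRanges`.
#' @param gap maximum separation in bp to close (>= 0).
#' @return a sorted, disjoint `GRanges`.
#' @export
mergeIntervals <- function(x, gap = 0L) {
  stopifnot(gap >= 0L)
  reduce(sort(x), min.gapwidth = gap + 1L, ignore.strand = TRUE)
}

#' Total shared bases between two merged interval sets
#'
#' Both inputs must be internally non-overlapping (pre-merged); the result is
#' symmetric.
#'
#' @param a,b `GRanges`, each internally disjoint.
#' @return shared base pairs (numeric scalar).
#' @export
overlapBp <- function(a, b) {
  if (!IRanges::isDisjoint(a, ignore.strand = TRUE) ||
      !IRanges::isDisjoint(b, ignore.strand = TRUE))
    stop("inputs must be merged (internally non-overlapping)")
  ov <- GenomicRanges::intersect(granges(a), granges(b), ignore.strand = TRUE)
  sum(as.numeric(width(ov)))
}

#' Complement of an interval set over a genome
#'
#' Returns the intervals not covered by `x`, so that input and output
#' together tile every chromosome exactly once.
#'
#' @param x a merged `GRanges`.
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @return a `GRanges` disjoint from `x`.
#' @export
complementIntervals <- function(x, genome) {
  whole <- GRanges(seqnames(genome), IRanges(1L, seqlengths(genome)),
                   seqinfo = genome)
  x <- .applyGenome(granges(x), genome)
  GenomicRanges::setdiff(whole, x, ignore.strand = TRUE)
}

#' Read gene models from GFF3
#'
#' Restricted to gene and CDS features; CDS records are assigned to their
#' gene via the `Parent`/`gene_id` attribute chain (mRNA features are used
#' only to resolve parentage).
#'
#' @param file path to a GFF3 file.
#' @param genome optional [GenomeInfoDb::Seqinfo].
#' @return a [GeneModelSet].
#' @export
readGeneModels <- function(file, genome = NULL) {
  gff <- rtracklayer::import(file, format = "gff3")
  gff <- .applyGenome(gff, genome)
  genes <- gff[gff$type == "gene"]
  names(genes) <- genes$ID
  mrna <- gff[gff$type == "mRNA"]
  mrna2gene <- setNames(as.character(unlist(mrna$Parent)), mrna$ID)
  cds <- gff[gff$type == "CDS"]
  if (length(cds)) {
    parent <- as.character(unlist(cds$Parent))
    gene_id <- ifelse(parent %in% names(mrna2gene), mrna2gene[parent], parent)
    cds <- granges(cds)
    mcols(cds)$gene_id <- unname(gene_id)
  } else {
    cds <- GRanges()
    mcols(cds)$gene_id <- character(0)
  }
  geneModelSet(granges(genes, use.names = TRUE), cds)
}

#' Construct a GeneModelSet
#'
#' @param genes named, stranded `GRanges` of gene bodies.
#' @param cds `GRanges` of CDS intervals with a `gene_id` column (may be
#'   empty).
#' @return a [GeneModelSet].
#' @export
geneModelSet <- function(genes, cds = GRanges(gene_id = character(0))) {
  if (!"gene_id" %in% names(mcols(cds))) mcols(cds)$gene_id <- character(0)
  new("GeneModelSet", genes = genes, cds = cds)
}

#' Read a genome FASTA
#'
#' @param file path to an (uncompressed or gzipped) FASTA file.
#' @return a `DNAStringSet` named by chromosome.
#' @export
readGenomeFasta <- function(file) {
  seqs <- readDNAStringSet(file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Seqinfo of a DNAStringSet genome
#'
#' @param sequences a named `DNAStringSet`.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
genomeOf <- function(sequences) {
  Seqinfo(seqnames = names(sequences),
          seqlengths = setNames(Biostrings::width(sequences),
                                names(sequences)))
}

#' Validate a file against a format
#'
#' Light-weight conformance check used by the `moa io-validate` command:
#' attempts a strict parse and reports the first problem found.
#'
#' @param file path to the file.
#' @param format one of `"bed"`, `"bedgraph"`, `"gff3"`, `"fasta"`,
#'   `"chromsizes"`, `"segments"`; `"auto"` guesses from the extension.
#' @return `TRUE` invisibly on success; stops with a message otherwise.
#' @export
ioValidate <- function(file, format = "auto") {
  if (!file.exists(file)) stop("no such file: ", file)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", file)))
    format <- switch(ext,
      bed = "bed", bedgraph = "bedgraph", bg = "bedgraph",
      gff = "gff3", gff3 = "gff3", fa = "fasta", fasta = "fasta",
      fai = "chromsizes", sizes = "chromsizes", tsv = "chromsizes",
      txt = "segments",
      stop("cannot guess format from extension '.", ext, "'"))
  }
  switch(format,
    bed = rtracklayer::import(file, format = "BED"),
    bedgraph = rtracklayer::import(file, format = "bedGraph"),
    gff3 = rtracklayer::import(file, format = "gff3"),
    fasta = readDNAStringSet(file),
    chromsizes = readChromSizes(file),
    segments = readSegmentTable(file),
    stop("unknown format: ", format))
  invisible(TRUE)
}
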