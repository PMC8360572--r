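---
title: "Footprint profiling from MNase fragment midpoints: models, parameters and design choices"
author: "moaseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint profiling from MNase fragment midpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the signal model, the
segmentation contract, what the synthetic generator does and does not
emulate, and the choices made where the design was genuinely open. It states
no empirical numbers beyond those the test suite and `scripts/acceptance.R`
compute themselves.

## 1. Signal model

MNase digestion of crosslinked chromatin is blocked wherever a protein is
bound. After a light digest and small-fragment size selection (≤ 80 bp), the
surviving fragments fall into two classes: linker/naked debris near the size
floor, and fragments protected by small non-nucleosomal particles
(10–25 bp TF footprints plus protruding unprotected overhangs). Nucleosomal
fragments (≥ 147 bp) are excluded by the size selection. A protected fragment
straddles the particle that protected it, so its geometric midpoint falls
near the particle's center; the density of midpoints — the *frenter track* —
peaks over occupied sites with a resolution far below the fragment length.

Two track kinds are produced:

* **coverage**: mean per-base fragment depth in `binWidth` = 10 bp bins. The
  per-base mean (rather than a read count per bin) makes the value invariant
  to bin width at uniform depth and directly displayable as bedGraph.
* **frenter**: count of fragment midpoints in 21 bp windows advanced by 5 bp.
  Windows overlap; each count is anchored to the 5 bp step-grid record at the
  window start, so records are disjoint and bedGraph-legal. Whether windows
  are anchored at zero or centered on grid points is not externally
  constrained; anchoring at multiples of the step was chosen and is the
  documented convention. Chromosome-edge windows are truncated without
  rescaling — this touches less than one window width per chromosome end.

Midpoints of even-length fragments have no integer center;
`floor((start + end) / 2)` (the left-of-center base, 0-based half-open
arithmetic) is used so window membership is exactly testable. Deduplication
keys on (chrom, start, end) only: the fragments are unstranded duplexes, and
paired-end duplicates share both ends regardless of read orientation. The
size filter is inclusive at the threshold ("≤ 80 bp" means 80 stays).

Normalization: CPM multiplies every record by `1e6 / library fragment
count`. Quantile normalization rank-matches the *non-zero* values onto the
reference's non-zero distribution (ties averaged), leaving zeros at zero —
at genome scale the zero class dominates and would otherwise distort the
upper tail, mirroring the zero-exclusion logic of the segmentation
statistics. Control subtraction is an elementwise difference that retains
negative values; the result is a signed track and is marked as such.

## 2. Segmentation and the biological cutoff

Peak calling standardizes each record, `z = (v - mean) / scale`, using
statistics computed over the track's non-zero *support* (optionally the
support of a pooled companion track), then:

1. enumerate every candidate segment of 20–120 bp on the record grid;
2. a candidate is significant when its mean `z` reaches the biological
   cutoff BC (so "height greater than BC × SD above the mean" — the
   mean-subtracted reading of the cutoff was chosen where the phrasing was
   ambiguous, and is asserted by the oracle tests);
3. score `t = mean(z) * sqrt(records)` and select non-overlapping candidates
   greedily by descending `t`, ties broken by smaller start then smaller
   width (ties are compared after rounding `t` to nine decimals so that
   mathematically equal scores are not reordered by floating-point noise);
4. merge surviving segments that are book-ended or separated by ≤ 1 bp;
   merged peaks recompute the mean height bp-weighted and keep the maximum
   constituent `t`.

The reported p-value is the one-sided standard-normal tail of `t`,
uncorrected: peaks are thresholded by BC, never by p; the column exists to
fill the six-column output convention (chrom, SegmentStart, SegmentEnd,
meanHeight, t-statistic, p-value). The sample SD (n−1) is the default scale;
the plain median absolute deviation (constant = 1, i.e. the literal median
of absolute deviations) is offered as a robust alternative.

An exhaustive brute-force reference implementation lives in the test suite
and the calling path must match it record-for-record on randomized tracks;
this is the package's primary correctness guarantee for the segmentation.

**Genomic-fraction equivalency.** Instead of a universal significance
threshold, the BC is calibrated so that called peaks capture a target
fraction of the genome, making peak sets comparable across datasets. The
packaged defaults are the conventional bands for maize-scale data:
0.5–0.7% of the genome for coverage peaks and 0.1–0.2% for frenter
footprints. Those bands encode a
*site density*: roughly (number of expected footprints) × (~30 bp footprint
width) / (genome size). For the synthetic template used in the acceptance
analyses (200 sites on 1 Mb) the same principle gives 200 × 25–35 bp =
0.5–0.7%, which is the band the acceptance harness passes to
`calibrateBc()`; the maize frenter band cannot transfer to a template whose
site density is twenty-fold higher. Among in-band cutoffs the most stringent
is returned; if no cutoff lands in the band the nearest is returned with a
warning.

## 3. The synthetic chromatin template

`buildTemplate()` emulates the features the analysis depends on:

* genes in evenly spaced slots (default 100 genes of 1–3 kb on 2 × 500 kb),
  each with a 350 bp nucleosome-free region (NFR) upstream of the TSS;
* nucleosomes tiled at 147 bp cores + 30 bp linkers everywhere else, with
  per-molecule occupancy 0.9 and positional jitter σ = 10 bp (jitter
  controls how sharp footprint peaks can be);
* TF sites of 10–25 bp: one per promoter NFR (80–290 bp upstream of the
  TSS), the remainder in their own intergenic accessible pockets. Each site
  carries an exact match to its motif consensus at its center, on a random
  strand. Promoter-site occupancy π is a monotone (rank-based) map of the
  host gene's log-normal expression into `piRange` — the mechanism behind
  the expression-quintile analysis. The linear π → signal assumption is a
  modeling choice, not an empirical claim;
* a few multi-kb repeat intervals, one anchored over an enhancer pocket so
  repeat/non-repeat splits are exercised.

`simulateDigest()` digests each molecule independently: every nucleosome and
TF site is occupied by a Bernoulli draw (occupancy × protection
completeness, default completeness 0.95), cut positions follow a Poisson
process on unprotected bases only, fragments are the intervals between
consecutive cuts, and the 30–80 bp class is retained, pooled and subsampled
to the requested depth. `simulateControl()` is the same process with no
protection and an optional multiplicative A/T cut-rate bias.

**The cut rate is deliberately heavy.** The model has no explicit
exonuclease step; the size selection stands in for trimming-to-footprint.
That substitution only works if unprotected DNA is shredded *below* the
30 bp retention floor — otherwise naked fragments are as long as the sites
are wide and midpoints do not concentrate at all. The default cut rate is
therefore 1/10 per unprotected bp (mean naked fragment 10 bp ≪ 30 bp floor),
under which a protected 10–25 bp site yields retained fragments of roughly
site + two short overhangs (~30–55 bp) with midpoints tightly packed at the
site center, while naked DNA contributes only the sparse tail that survives
the floor. 250 molecules produce ≈ 300k retained fragments on the default
template.

What the simulator does **not** emulate: sequencing reads and mapping error,
end-resection noise at cut sites, crosslinking chemistry, GC-dependent
amplification, overlapping/competing binding sites, and any coupling between
nucleosome occupancy and expression. Passing tests therefore demonstrate the
*pipeline's* correctness and sensitivity under a clean generative model, not
performance on real libraries.

## 4. Aggregation, classification, motifs

Metagene profiles rescale each gene body to 2000 positions by
nearest-source-base lookup (`floor(j·L/body)`) — exact and testable, no
interpolation — with flanks in real bp and minus-strand genes reversed.
Metapeak profiles use the rounded mean input width as the common size.
Expression quintiles rank genes by descending expression (ties broken
stably by gene id; missing values count as 0); quintile 1 is the
highest-expressed fifth and group sizes differ by at most one.

Footprint classification assigns each peak exactly one category by priority:
CDS overlap → `coding`; gene-body overlap → `gene_other`; within 2000 bp of
a gene boundary → `flanking`; else `intergenic`. The flanking distance is
not externally fixed; 2 kb (a conventional promoter/terminator window) is
the default and is calibration-sensitive. The four-way taxonomy is a deliberately coarse,
fully reproducible scheme; finer genomic taxonomies can be layered on top
of the per-peak assignments it returns.

Motif scanning matches IUPAC consensus strings (oligos) or
`left N^s right` for every spacer `s` in a dyad's range, on both strands,
keeping overlapping and palindromic double hits; sites are named
`name_motifConsensus_ExactLocalSeq` with the local sequence read in motif
orientation. Enrichment folds are midpoint-assigned density ratios,
`(nTarget/bpTarget) / (nSpace/bpSpace)`, against either the (optionally
mappability-restricted) whole genome or the non-ORF promoter space: up to
3 kb upstream of each TSS, truncated at the first CDS obstruction on the
TSS-proximal side. The density ratio is exactly 1 when target
equals space and scales correctly with unequal region sizes, which is why
it was chosen as the fold definition. Repeat membership is any-overlap
(≥ 1 bp).

## 5. Acceptance analyses and problem sizes

The acceptance harness (tests and `scripts/acceptance.R`) uses:

* segmentation oracle: 200 random tracks of ≤ 500 records, mixed sparsity;
* footprint recovery: the default 2 × 500 kb, 200-site template with
  occupancies in [0.8, 0.98], 300k fragments, calibration band 0.5–0.7%;
* reproducibility: two digest seeds of one template plus a naked control at
  the same depth, compared on 10 bp CPM coverage over non-zero-union bins;
* motif enrichment: an 800-site template (18–25 bp sites so the planted
  6-mer is always interior) scanned for the planted consensus and a
  letter-shuffled control;
* quintiles: a gene-dense template (250 genes of 1–2 kb, one promoter site
  each). With the default 100 genes the adjacent-quintile differences are
  comparable to their sampling noise, so the mean upstream coverage is
  estimated from 50 genes per quintile — a statistical-power choice, fixed
  before the analyses and not revisited per run.

These sizes keep each analysis in the tens of seconds on one CPU while
leaving the measured margins (recovery, correlations, folds, ordering)
comfortably away from their thresholds.

## 6. Numerical and degenerate-input behavior

* Intervals are clipped to chromosome bounds on read, with a warning.
* Strand `"."`/`"*"` is treated as `"+"` wherever orientation matters.
* An empty fragment set yields an all-zero track (warning, not error); CPM
  on a zero-fragment library, correlation of a constant vector, FRiP of an
  empty library, base sharing with an empty peak set, and segmentation with
  zero scale all raise errors.
* `filterBySize(maxLen = 0)` is the documented "all sizes" sentinel.
* Quantile normalization with a single non-zero value maps it to the
  reference median.
* `evaluateTruth()` summarizes the per-peak center error as the median over
  all called peaks (the summary population was unspecified; this choice
  penalizes false-positive peaks rather than hiding them).

## 7. Known limitations

Segmentation enumerates windows on the record grid, so peak boundaries are
quantized to the step (5 bp for frenter tracks); sub-step boundary precision
is not claimed. The greedy selection is optimal per score ordering, not a
global optimum. Negative-peak (nuclease-resistant) calling on signed
subtracted tracks is out of scope, as are de-novo motif discovery, PWM
log-odds scoring and database similarity search: the motif module scans and
evaluates given consensus models only.
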