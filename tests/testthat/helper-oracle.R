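# Independent brute-force segmentation reference: enumerates every
# (start, end) candidate on the record grid, applies the same threshold,
# scoring, tie-break and merge rules as the contract states, with none of the
# cumulative-sum machinery of the implementation.

bruteForceSegments <- function(values, mu, s, bc, minWindow = 20L,
                               maxWindow = 120L, step = 10L, mergeGap = 1L) {
  n <- length(values)
  z <- (values - mu) / s
  cand <- list()
  for (st in seq_len(n)) {
    for (en in st:n) {
      wbp <- (en - st + 1L) * step
      if (wbp < minWindow) next
      if (wbp > maxWindow) break
      mz <- mean(z[st:en])
      if (mz >= bc - 1e-9)
        cand[[length(cand) + 1L]] <- data.frame(start = st, end = en,
                                                meanZ = mz,
                                                t = mz * sqrt(en - st + 1L))
    }
  }
  if (length(cand) == 0L)
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      meanHeight = numeric(0), tStat = numeric(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-round(cand$t, 9), cand$start, cand$end - cand$start), ]
  occupied <- logical(n)
  sel <- list()
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start[i]:cand$end[i]
    if (!any(occupied[idx])) {
      occupied[idx] <- TRUE
      sel[[length(sel) + 1L]] <- cand[i, ]
    }
  }
  sel <- do.call(rbind, sel)
  sel <- sel[order(sel$start), ]
  # convert to bp, then merge book-ended/<= mergeGap-separated segments
  segs <- data.frame(start0 = (sel$start - 1L) * step,
                     end0 = sel$end * step,
                     meanHeight = mu + sel$meanZ * s,
                     tStat = sel$t)
  if (nrow(segs) > 1L) {
    out <- segs[1, ]
    for (i in 2:nrow(segs)) {
      gap <- segs$start0[i] - out$end0[nrow(out)]
      if (gap <= mergeGap) {
        j <- nrow(out)
        w1 <- out$end0[j] - out$start0[j]
        w2 <- segs$end0[i] - segs$start0[i]
        out$meanHeight[j] <- (out$meanHeight[j] * w1 +
                              segs$meanHeight[i] * w2) / (w1 + w2)
        out$tStat[j] <- max(out$tStat[j], segs$tStat[i])
        out$end0[j] <- segs$end0[i]
      } else {
        out <- rbind(out, segs[i, ])
      }
    }
    segs <- out
  }
  rownames(segs) <- NULL
  segs
}

# Random sparse test tracks for the oracle-equivalence property
randomTrack <- function(nBins, step = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sparsity <- runif(1, 0.05, 0.6)
  v <- rpois(nBins, 1.2) * rbinom(nBins, 1L, sparsity)
  nSpikes <- sample(0:8, 1)
  if (nSpikes > 0) {
    at <- sample(nBins, nSpikes)
    v[at] <- v[at] + rpois(nSpikes, 12)
  }
  if (sum(v != 0) < 3L) v[sample(nBins, 3L)] <- c(2, 5, 9)
  makeTrack(list(chrT = as.numeric(v)), step = step)
}
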