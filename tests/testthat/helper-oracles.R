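# Independent oracles used to cross-check the implementation.

# Brute-force event enumeration: a literal, loop-based restatement of the
# event rules (maximal supra-threshold runs, gap merging, length filter,
# onset / peak-until-local-minimum / pre-onset-median amplitude), written
# independently of the package's vectorized path.
bruteForceEvents <- function(dff, d, thresholds, minSeparation = 2,
                             minEventFrames = 1, localBaselineWindow = 5) {
  rows <- list()
  n <- nrow(dff)
  for (c in seq_len(ncol(dff))) {
    id <- colnames(dff)[c]
    thr <- thresholds[[id]]
    above <- d[, c] > thr
    # maximal runs by explicit scan (1-based d rows)
    runs <- list()
    i <- 1L
    while (i <= length(above)) {
      if (isTRUE(above[i])) {
        j <- i
        while (j < length(above) && isTRUE(above[j + 1L])) j <- j + 1L
        runs[[length(runs) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    # merge runs separated by fewer than minSeparation sub-threshold frames
    merged <- list()
    for (r in runs) {
      if (length(merged)) {
        last <- merged[[length(merged)]]
        if (r[1L] - last[2L] - 1L < minSeparation) {
          merged[[length(merged)]] <- c(last[1L], r[2L])
          next
        }
      }
      merged[[length(merged) + 1L]] <- r
    }
    # drop events with too few supra-threshold frames
    kept <- list()
    for (r in merged) {
      cnt <- 0L
      for (k in r[1L]:r[2L]) if (above[k]) cnt <- cnt + 1L
      if (cnt >= minEventFrames) kept[[length(kept) + 1L]] <- c(r, cnt)
    }
    for (i in seq_along(kept)) {
      r <- kept[[i]]
      onset0 <- r[1L]                      # 0-based frame the run lands on
      land0 <- r[2L]
      stop0 <- n - 1L
      f <- land0
      while (f < n - 1L) {
        if (dff[f + 1L, c] <= dff[f + 2L, c]) { stop0 <- f; break }
        f <- f + 1L
      }
      if (i < length(kept)) stop0 <- min(stop0, kept[[i + 1L]][1L] - 1L)
      stop0 <- max(stop0, onset0)
      best <- onset0
      for (f in onset0:stop0)
        if (dff[f + 1L, c] > dff[best + 1L, c]) best <- f
      lo <- onset0 - localBaselineWindow
      if (lo < 0L) lo <- 0L
      base <- if (onset0 == 0L) 0 else median(dff[(lo + 1L):onset0, c])
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id, onset_frame = onset0, peak_frame = best,
        amplitude = dff[best + 1L, c] - base, duration = r[3L],
        threshold = thr, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = character(0), onset_frame = integer(0),
                      peak_frame = integer(0), amplitude = numeric(0),
                      duration = integer(0), threshold = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Greedy matcher: truth spikes matched to the earliest unused detected onset
# within a +/- tol frame window; returns pooled counts.
matchEvents <- function(events, truth, tol = 2) {
  tp <- 0L; fn <- 0L; fp <- 0L
  ids <- unique(c(truth$cell_id, events$cell_id))
  for (id in ids) {
    t0 <- truth$frame[truth$cell_id == id]
    de <- events$onset_frame[events$cell_id == id]
    used <- rep(FALSE, length(de))
    for (t in t0) {
      j <- which(!used & abs(de - t) <= tol)
      if (length(j)) { used[j[1L]] <- TRUE; tp <- tp + 1L } else fn <- fn + 1L
    }
    fp <- fp + sum(!used)
  }
  list(tp = tp, fn = fn, fp = fp,
       f1 = if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn))
}

# build a NormalizedTrace directly from a dff matrix (reference frame 0)
ntFromDff <- function(dff) {
  dff[1L, ] <- 0
  F <- 100 * (1 + dff)
  normalizeTrace(TraceSet(seq_len(nrow(dff)) - 1, F))
}

# closed-form log-normal bin masses for the bins binAmplitudes() emits
lnormBinMasses <- function(binEdges, meanlog, sdlog) {
  ed <- c(-Inf, binEdges, Inf)
  p <- numeric(length(ed) - 1L)
  for (i in seq_along(p))
    p[i] <- plnorm(ed[i + 1L], meanlog, sdlog) - plnorm(ed[i], meanlog, sdlog)
  p
}
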