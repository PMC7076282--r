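#' Normalize raw traces to the first baseline frame
#'
#' Divides every cell's raw fluorescence by its intensity at a reference
#' frame (by default the first frame of the baseline), yielding F/F0
#' (\code{norm}, equal to 1 at the reference frame) and dF/F0
#' (\code{dff} = F/F0 - 1). Cells whose reference intensity is zero or
#' negative cannot be normalized; they are excluded with a logged reason
#' (see [excludedCells()]), never silently.
#'
#' @param trace a [TraceSet-class].
#' @param referenceFrame 0-based index of the reference frame (default 0,
#'   the first frame of the recording/baseline).
#' @return a [NormalizedTrace-class].
#' @examples
#' ts <- TraceSet(0:4, matrix(c(100, 150, 100, 100, 100), 5, 1))
#' dffValues(normalizeTrace(ts))[2, ]   # 0.5
#' @export
normalizeTrace <- function(trace, referenceFrame = 0L) {
  stopifnot(is(trace, "TraceSet"))
  referenceFrame <- assertCount(referenceFrame, "referenceFrame",
                                positive = FALSE)
  if (referenceFrame >= nFrames(trace))
    stop("referenceFrame out of range", call. = FALSE)
  F <- traceValues(trace)
  f0 <- F[referenceFrame + 1L, ]
  bad <- f0 <= 0
  excluded <- character(0)
  if (any(bad)) {
    excluded <- stats::setNames(
      rep("non-positive reference intensity", sum(bad)),
      colnames(F)[bad])
    warning(sprintf("excluding %d cell(s) with non-positive reference intensity: %s",
                    sum(bad), paste(colnames(F)[bad], collapse = ", ")),
            call. = FALSE)
    F <- F[, !bad, drop = FALSE]
    f0 <- f0[!bad]
    if (ncol(F) == 0L) stop("no cells left after normalization", call. = FALSE)
  }
  norm <- sweep(F, 2L, f0, "/")
  new("NormalizedTrace", times = traceTimes(trace), norm = norm,
      dff = norm - 1, f0 = f0, refFrame = referenceFrame,
      excluded = excluded)
}

#' @rdname firstDerivative
#' @export
setMethod("firstDerivative", "NormalizedTrace", function(x, ...) {
  diff(x@dff)
})

#' @rdname firstDerivative
#' @export
setMethod("firstDerivative", "matrix", function(x, ...) {
  if (nrow(x) < 2L) stop("at least 2 frames are required", call. = FALSE)
  diff(x)
})

#' Per-cell event-detection threshold: quiet mean + k x SD
#'
#' Computes, for every cell, the detection threshold
#' \code{mean(d) + kSd * SD(d)} over transient-free ("quiet") frames of the
#' derivative signal. The SD is the population (divide-by-n) SD. The quiet
#' frames are either given explicitly or found automatically: starting from
#' the candidate (baseline) frames, frames whose derivative exceeds the
#' current threshold are excluded and the threshold recomputed, iterating to
#' a fixpoint (or \code{maxIter}).
#'
#' @param d derivative matrix from [firstDerivative()] ((frames - 1) x cells;
#'   row t corresponds to the change landing on 0-based frame t).
#' @param kSd threshold multiplier (default 2).
#' @param quietFrames explicit quiet region: 0-based derivative-row indices
#'   (i.e. values in \code{0 .. nrow(d) - 1}), or NULL for automatic mode.
#' @param baselineFrames candidate frames for automatic mode (same indexing);
#'   default all derivative rows.
#' @param maxIter maximum automatic-mode iterations.
#' @param minQuiet minimum number of quiet frames required (default 5).
#' @return named numeric vector of per-cell thresholds (derivative units),
#'   with the converged quiet frame sets in attribute \code{"quietFrames"}.
#' @examples
#' d <- matrix(c(-0.05, 0.05, -0.05, 0.05, 0), 5, 1)
#' estimateThreshold(d, kSd = 2, quietFrames = 0:4)  # 0.0894
#' @export
estimateThreshold <- function(d, kSd = 2, quietFrames = NULL,
                              baselineFrames = NULL, maxIter = 10,
                              minQuiet = 5) {
  d <- as.matrix(d)
  assertScalar(kSd, "kSd", lower = 1e-12)
  maxIter <- assertCount(maxIter, "maxIter")
  thr <- stats::setNames(numeric(ncol(d)), colnames(d))
  quietOut <- vector("list", ncol(d))
  names(quietOut) <- colnames(d)
  explicit <- !is.null(quietFrames)
  cand0 <- if (explicit) as.integer(quietFrames)
           else as.integer(baselineFrames %||% (seq_len(nrow(d)) - 1L))
  if (any(cand0 < 0L | cand0 >= nrow(d)))
    stop("quiet/baseline frame indices out of range (0-based derivative rows)",
         call. = FALSE)
  for (c in seq_len(ncol(d))) {
    quiet <- cand0 + 1L  # to 1-based rows
    if (length(quiet) < minQuiet)
      stop("insufficient quiet frames (need >= 5)", call. = FALSE)
    for (it in seq_len(if (explicit) 1L else maxIter)) {
      x <- d[quiet, c]
      m <- mean(x)
      s <- popSd(x)
      t <- m + kSd * s
      if (explicit) break
      keep <- quiet[d[quiet, c] <= t]
      if (length(keep) < minQuiet)
        stop("insufficient quiet frames (need >= 5)", call. = FALSE)
      if (length(keep) == length(quiet)) { quiet <- keep; break }
      quiet <- keep
    }
    x <- d[quiet, c]
    m <- mean(x)
    s <- popSd(x)
    if (s == 0 && any(d[-quiet, c] != 0)) {
      warning(sprintf(
        "cell '%s': zero quiet SD with nonzero signal elsewhere; threshold = quiet mean",
        colnames(d)[c] %||% as.character(c)), call. = FALSE)
      thr[c] <- m
    } else {
      thr[c] <- m + kSd * s
    }
    quietOut[[c]] <- quiet - 1L
  }
  attr(thr, "quietFrames") <- quietOut
  thr
}

# maximal runs of TRUE in a logical vector -> list of (start, end) 1-based
runsOf <- function(above) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Map(c, starts[keep], ends[keep])
}

# merge runs separated by fewer than minSeparation below-threshold frames
mergeRuns <- function(runs, minSeparation) {
  if (length(runs) <= 1L) return(runs)
  out <- list(runs[[1L]])
  for (i in seq_along(runs)[-1L]) {
    prev <- out[[length(out)]]
    gap <- runs[[i]][1L] - prev[2L] - 1L
    if (gap < minSeparation)
      out[[length(out)]] <- c(prev[1L], runs[[i]][2L])
    else out <- c(out, list(runs[[i]]))
  }
  out
}

#' Detect calcium transients from supra-threshold derivative runs
#'
#' Implements the derivative-threshold event rule: maximal runs of
#' derivative frames strictly above the per-cell threshold (positive side
#' only) become candidate events; runs separated by fewer than
#' \code{minSeparation} sub-threshold frames are merged; merged runs with
#' fewer than \code{minEventFrames} supra-threshold frames are discarded.
#' For each event (0-based frames throughout):
#' \itemize{
#'   \item \code{onset_frame} — the frame the first supra-threshold
#'     derivative step lands on;
#'   \item \code{peak_frame} — argmax of dF/F0 from onset up to the first
#'     local minimum of dF/F0 after the run (truncated before the next
#'     event's onset, so events of one cell never overlap);
#'   \item \code{amplitude} — dF/F0 at the peak minus the median dF/F0 over
#'     the \code{localBaselineWindow} frames before onset (window clipped at
#'     the recording start; 0, the reference level, if empty);
#'   \item \code{duration} — number of supra-threshold derivative frames.
#' }
#' Cells without events simply contribute no rows.
#'
#' @param nt a [NormalizedTrace-class].
#' @param d derivative matrix from [firstDerivative()] (recomputed if NULL).
#' @param threshold per-cell thresholds from [estimateThreshold()] (a named
#'   vector, recycled if scalar).
#' @param minSeparation merge runs separated by fewer than this many frames
#'   (default 2).
#' @param minEventFrames minimum supra-threshold frames per event (default 1).
#' @param localBaselineWindow pre-onset window (frames) for the amplitude
#'   baseline (default 5).
#' @return data frame with columns \code{cell_id, onset_frame, peak_frame,
#'   amplitude, duration, threshold}.
#' @export
detectEvents <- function(nt, d = NULL, threshold, minSeparation = 2,
                         minEventFrames = 1, localBaselineWindow = 5) {
  stopifnot(is(nt, "NormalizedTrace"))
  if (is.null(d)) d <- firstDerivative(nt)
  minSeparation <- assertCount(minSeparation, "minSeparation")
  minEventFrames <- assertCount(minEventFrames, "minEventFrames")
  localBaselineWindow <- assertCount(localBaselineWindow,
                                     "localBaselineWindow")
  dff <- nt@dff
  ids <- colnames(dff)
  threshold <- if (length(threshold) == 1L)
    stats::setNames(rep(threshold, ncol(dff)), ids) else threshold
  if (!all(ids %in% names(threshold)))
    stop("a threshold is required for every analyzed cell", call. = FALSE)
  n <- nrow(dff)
  res <- list()
  for (c in seq_along(ids)) {
    thr <- threshold[[ids[c]]]
    runs <- runsOf(d[, c] > thr)
    runs <- mergeRuns(runs, minSeparation)
    if (!length(runs)) next
    width <- vapply(runs, function(r)
      sum(d[r[1L]:r[2L], c] > thr), integer(1))
    keep <- width >= minEventFrames
    runs <- runs[keep]
    width <- width[keep]
    if (!length(runs)) next
    onsets <- vapply(runs, `[`, numeric(1), 1L)        # 0-based frame = row
    nextOnset <- c(onsets[-1L], Inf)
    ev <- vector("list", length(runs))
    for (i in seq_along(runs)) {
      onset0 <- as.integer(runs[[i]][1L])              # 0-based onset frame
      land0 <- as.integer(runs[[i]][2L])               # 0-based landing frame
      # first local minimum of dff after the run bounds the peak search
      stop0 <- n - 1L
      f <- land0
      while (f < n - 1L) {
        if (dff[f + 1L, c] <= dff[f + 2L, c]) { stop0 <- f; break }
        f <- f + 1L
      }
      if (is.finite(nextOnset[i]))
        stop0 <- min(stop0, as.integer(nextOnset[i]) - 1L)
      stop0 <- max(stop0, onset0)
      seg <- dff[(onset0 + 1L):(stop0 + 1L), c]
      peak0 <- onset0 + which.max(seg) - 1L
      lo <- max(0L, onset0 - localBaselineWindow)
      base <- if (onset0 == 0L) 0
              else stats::median(dff[(lo + 1L):onset0, c])
      ev[[i]] <- data.frame(cell_id = ids[c], onset_frame = onset0,
                            peak_frame = peak0,
                            amplitude = dff[peak0 + 1L, c] - base,
                            duration = width[i], threshold = thr,
                            stringsAsFactors = FALSE)
    }
    res <- c(res, ev)
  }
  if (!length(res))
    return(data.frame(cell_id = character(0), onset_frame = integer(0),
                      peak_frame = integer(0), amplitude = numeric(0),
                      duration = integer(0), threshold = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-cell activity summary: spikes per 4-minute window and abolition
#'
#' Counts, per cell, the events whose onset falls in a window of
#' \code{window} seconds at the start of the baseline epoch (the
#' "spikes / 4 min" statistic), and assesses, for every later epoch, whether
#' activity was abolished: the event rate in the treatment epoch must not
#' exceed \code{abolitionFraction} times the baseline rate (default 0 —
#' strict abolition, i.e. no treatment-epoch events at all).
#'
#' @param events event table from [detectEvents()].
#' @param plan an [EpochPlan-class]; the first epoch is taken as baseline
#'   unless \code{baselineLabel} says otherwise.
#' @param dt frame interval, seconds.
#' @param cellIds cells to summarize (so silent cells appear with zero
#'   counts); defaults to the cells present in \code{events}.
#' @param window counting window, seconds (default 240 = 4 min); must fit
#'   inside the baseline epoch.
#' @param baselineLabel baseline epoch label.
#' @param abolitionFraction tolerated treatment/baseline rate ratio.
#' @return data frame: \code{cell_id, spikes_per_4min, n_events_total,
#'   mean_amplitude, threshold_used} plus one logical
#'   \code{abolished_<label>} column per non-baseline epoch.
#' @export
summarizeActivity <- function(events, plan, dt = 1, cellIds = NULL,
                              window = 240, baselineLabel = NULL,
                              abolitionFraction = 0) {
  assertScalar(window, "window", lower = 1e-12)
  baselineLabel <- baselineLabel %||% epochLabels(plan)[1L]
  bw <- epochWindow(plan, baselineLabel)
  wFrames <- window / dt
  if (wFrames > bw[["end"]] - bw[["start"]])
    stop(sprintf("window (%g s) is longer than the '%s' epoch",
                 window, baselineLabel), call. = FALSE)
  cellIds <- cellIds %||% unique(events$cell_id)
  others <- setdiff(epochLabels(plan), baselineLabel)
  out <- lapply(cellIds, function(id) {
    ev <- events[events$cell_id == id, , drop = FALSE]
    inWin <- ev$onset_frame >= bw[["start"]] &
             ev$onset_frame < bw[["start"]] + wFrames
    inBase <- ev$onset_frame >= bw[["start"]] & ev$onset_frame < bw[["end"]]
    baseRate <- sum(inBase) / ((bw[["end"]] - bw[["start"]]) * dt)
    row <- data.frame(cell_id = id, spikes_per_4min = sum(inWin),
                      n_events_total = nrow(ev),
                      mean_amplitude = if (nrow(ev)) mean(ev$amplitude)
                                       else NA_real_,
                      threshold_used = if (nrow(ev)) ev$threshold[1L]
                                       else NA_real_,
                      stringsAsFactors = FALSE)
    for (lab in others) {
      w <- epochWindow(plan, lab)
      nTreat <- sum(ev$onset_frame >= w[["start"]] &
                    ev$onset_frame < w[["end"]])
      rate <- nTreat / ((w[["end"]] - w[["start"]]) * dt)
      row[[paste0("abolished_", lab)]] <- rate <= abolitionFraction * baseRate
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin transient amplitudes into histogram proportions
#'
#' Bins amplitudes (dF/F0 units) into half-open bins \code{[e_i, e_{i+1})}
#' defined by sorted edges, per condition. Values below the first edge and
#' at/above the last edge go to explicit \code{underflow} / \code{overflow}
#' rows, so proportions always sum to exactly 1 per condition.
#'
#' @param amplitudes numeric vector of event amplitudes, or an event table
#'   with an \code{amplitude} column.
#' @param binEdges strictly increasing numeric bin edges.
#' @param condition optional grouping (recycled against amplitudes); e.g.
#'   culture age.
#' @return data frame: \code{condition, bin, lower, upper, count,
#'   proportion}.
#' @examples
#' binAmplitudes(c(0.2, 0.2, 0.8), c(0, 0.5, 1))
#' @export
binAmplitudes <- function(amplitudes, binEdges, condition = NULL) {
  if (is.data.frame(amplitudes)) {
    if (is.null(condition) && !is.null(amplitudes$condition))
      condition <- amplitudes$condition
    amplitudes <- amplitudes$amplitude
  }
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (length(binEdges) < 2L) stop("need at least 2 bin edges", call. = FALSE)
  condition <- rep_len(if (is.null(condition)) "all" else
                       as.character(condition), length(amplitudes))
  nb <- length(binEdges) - 1L
  out <- lapply(unique(condition), function(g) {
    x <- amplitudes[condition == g]
    if (!length(x)) stop(sprintf("condition '%s' has no events", g),
                         call. = FALSE)
    idx <- findInterval(x, binEdges)         # 0 = underflow, nb+1 = overflow
    cnt <- tabulate(idx + 1L, nbins = nb + 2L)
    data.frame(condition = g,
               bin = c("underflow",
                       sprintf("[%g,%g)", binEdges[-(nb + 1L)],
                               binEdges[-1L]),
                       "overflow"),
               lower = c(-Inf, binEdges[-(nb + 1L)], binEdges[nb + 1L]),
               upper = c(binEdges[1L], binEdges[-1L], Inf),
               count = cnt, proportion = cnt / length(x),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-call transient analysis of a recording
#'
#' Convenience wrapper chaining [normalizeTrace()], [firstDerivative()],
#' automatic [estimateThreshold()] over the baseline epoch,
#' [detectEvents()] and [summarizeActivity()].
#'
#' The published event criterion ("positive derivative value of 2 x SD +
#' average in regions devoid of transients") is read, by default, as a
#' threshold on the first-derivative signal with both statistics computed on
#' quiet derivative frames (\code{statistic = "derivative"}). The alternative
#' reading — statistics computed on, and threshold applied to, the normalized
#' intensity itself — is available with \code{statistic = "intensity"}.
#'
#' @param trace a [TraceSet-class].
#' @param plan an [EpochPlan-class]; first epoch = baseline.
#' @param kSd threshold multiplier.
#' @param window spikes-per-window counting window, seconds.
#' @param abolitionFraction see [summarizeActivity()].
#' @param referenceFrame 0-based normalization reference; default the first
#'   baseline frame.
#' @param statistic \code{"derivative"} (default) or \code{"intensity"}.
#' @param detrend optional exponential-bleach detrend before analysis
#'   (default FALSE; fits \code{log F ~ t} on the baseline epoch and divides
#'   it out).
#' @param smoothWindow optional moving-average pre-filter width (frames)
#'   applied to dF/F0 before differentiation; default 1 (no smoothing).
#' @param ... passed to [detectEvents()].
#' @return list: \code{events}, \code{summary}, \code{thresholds},
#'   \code{normalized}.
#' @export
detectTransients <- function(trace, plan, kSd = 2, window = 240,
                             abolitionFraction = 0, referenceFrame = NULL,
                             statistic = c("derivative", "intensity"),
                             detrend = FALSE, smoothWindow = 1, ...) {
  statistic <- match.arg(statistic)
  dt <- frameInterval(trace)
  baseW <- epochWindow(plan, epochLabels(plan)[1L])
  referenceFrame <- referenceFrame %||% baseW[["start"]]
  if (detrend) trace <- detrendExponential(trace, plan)
  nt <- normalizeTrace(trace, referenceFrame = referenceFrame)
  dff <- nt@dff
  if (smoothWindow > 1) {
    k <- rep(1 / smoothWindow, smoothWindow)
    sm <- apply(dff, 2L, function(x)
      stats::filter(x, k, sides = 2L))
    sm[is.na(sm)] <- dff[is.na(sm)]
    dff <- sm
    dimnames(dff) <- dimnames(nt@dff)
  }
  d <- diff(dff)
  if (statistic == "derivative") {
    # derivative rows fully inside the baseline epoch (0-based rows s..e-2)
    cand <- seq.int(baseW[["start"]], baseW[["end"]] - 2L)
    thr <- estimateThreshold(d, kSd = kSd, baselineFrames = cand)
    events <- detectEvents(nt, d = d, threshold = thr, ...)
  } else {
    cand <- seq.int(baseW[["start"]], baseW[["end"]] - 1L)
    thr <- estimateThresholdIntensity(dff, kSd = kSd, baselineFrames = cand)
    events <- detectEventsIntensity(nt, dff, thr, ...)
  }
  summary <- summarizeActivity(events, plan, dt = dt,
                               cellIds = cellIds(nt), window = window,
                               abolitionFraction = abolitionFraction)
  list(events = events, summary = summary, thresholds = thr, normalized = nt)
}

# alternative reading: statistics on (and threshold applied to) the
# normalized intensity itself
estimateThresholdIntensity <- function(dff, kSd = 2, baselineFrames = NULL,
                                       maxIter = 10, minQuiet = 5) {
  estimateThreshold(dff, kSd = kSd, baselineFrames = baselineFrames,
                    maxIter = maxIter, minQuiet = minQuiet)
}

detectEventsIntensity <- function(nt, dff, threshold, minSeparation = 2,
                                  minEventFrames = 1,
                                  localBaselineWindow = 5) {
  ids <- colnames(dff)
  res <- list()
  for (c in seq_along(ids)) {
    thr <- threshold[[ids[c]]]
    runs <- mergeRuns(runsOf(dff[, c] > thr), minSeparation)
    if (!length(runs)) next
    for (r in runs) {
      if (r[2L] - r[1L] + 1L < minEventFrames) next
      onset0 <- r[1L] - 1L
      seg <- dff[r[1L]:r[2L], c]
      peak0 <- onset0 + which.max(seg) - 1L
      lo <- max(0L, onset0 - localBaselineWindow)
      base <- if (onset0 == 0L) 0 else stats::median(dff[(lo + 1L):onset0, c])
      res <- c(res, list(data.frame(
        cell_id = ids[c], onset_frame = onset0, peak_frame = peak0,
        amplitude = dff[peak0 + 1L, c] - base,
        duration = r[2L] - r[1L] + 1L, threshold = thr,
        stringsAsFactors = FALSE)))
    }
  }
  if (!length(res))
    return(data.frame(cell_id = character(0), onset_frame = integer(0),
                      peak_frame = integer(0), amplitude = numeric(0),
                      duration = integer(0), threshold = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Optional exponential bleach detrend
#'
#' Fits log(F) ~ time on the baseline epoch per cell and divides the fitted
#' exponential out of the whole trace. Off by default in the pipeline; the
#' standard analysis applies no detrending.
#'
#' @param trace a [TraceSet-class].
#' @param plan an [EpochPlan-class] (the first epoch is used for the fit).
#' @return a detrended [TraceSet-class].
#' @export
detrendExponential <- function(trace, plan) {
  w <- epochWindow(plan, epochLabels(plan)[1L])
  idx <- seq.int(w[["start"]] + 1L, w[["end"]])
  F <- traceValues(trace)
  t <- traceTimes(trace)
  out <- F
  for (c in seq_len(ncol(F))) {
    y <- F[idx, c]
    if (any(y <= 0)) next
    fit <- stats::lm.fit(cbind(1, t[idx]), log(y))
    rate <- fit$coefficients[2L]
    if (rate < 0) out[, c] <- F[, c] / exp(rate * (t - t[1L]))
  }
  TraceSet(t, out, dye = trace@meta$dye %||% "Fluo-4",
           meta = utils::modifyList(trace@meta, list(detrended = TRUE)))
}
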