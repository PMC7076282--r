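#' Compute the 340/380 excitation ratio
#'
#' R = F340 / F380 per frame and cell. Frames with non-positive F380 cannot
#' form a ratio; they are returned as NA (and counted in attribute
#' \code{"flaggedFrames"}), so they are excluded from all downstream
#' statistics rather than silently contaminating them.
#'
#' @param rt a [RatioTraceSet-class].
#' @return numeric matrix frames x cells of ratios, NA where flagged.
#' @examples
#' rt <- RatioTraceSet(0:2, matrix(2, 3, 1), matrix(4, 3, 1))
#' computeRatio(rt)[1, ]   # 0.5
#' @export
computeRatio <- function(rt) {
  stopifnot(is(rt, "RatioTraceSet"))
  R <- rt@f340 / rt@f380
  bad <- rt@f380 <= 0
  if (any(bad)) {
    R[bad] <- NA_real_
    warning(sprintf("%d frame(s) with non-positive F380 flagged (NA ratio)",
                    sum(bad)), call. = FALSE)
  }
  attr(R, "flaggedFrames") <- colSums(bad)
  R
}

# median of the k largest finite values
medianTopK <- function(x, k) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  stats::median(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))])
}

#' Estimate per-cell Grynkiewicz calibration constants
#'
#' From the two calibration epochs of a SOCE recording: Rmax is the median of
#' the \code{kFrames} largest ratios in the ionomycin (dye-saturating) epoch;
#' Rmin is the median of the last \code{kFrames} ratios of the EGTA
#' (Ca2+-free) epoch; the per-cell scaling factor SF is the median F380 over
#' the Rmin window (Ca2+-free form) divided by the median F380 over the
#' frames providing Rmax (Ca2+-bound form). Kd is passed through (default
#' 225 nM, the Fura-2 value used for human cells). Cells with
#' \code{rmin >= rmax} are flagged invalid, not dropped.
#'
#' @param R ratio matrix from [computeRatio()].
#' @param rt the [RatioTraceSet-class] the ratios came from (for F380).
#' @param plan an [EpochPlan-class] containing \code{iono} and \code{egta}
#'   epochs (a missing epoch is a hard error).
#' @param kd dye dissociation constant, nM.
#' @param kFrames extreme-frame window for the robust Rmin/Rmax estimates.
#' @param ionoLabel,egtaLabel epoch labels.
#' @return a [CalibrationParams-class].
#' @export
estimateCalibration <- function(R, rt, plan, kd = 225, kFrames = 5,
                                ionoLabel = "iono", egtaLabel = "egta") {
  stopifnot(is(rt, "RatioTraceSet"))
  assertScalar(kd, "kd", lower = 1e-12)
  kFrames <- assertCount(kFrames, "kFrames")
  for (lab in c(ionoLabel, egtaLabel))
    if (!hasEpoch(plan, lab))
      stop(sprintf("calibration requires an epoch labelled '%s'", lab),
           call. = FALSE)
  ii <- epochFrames(plan, ionoLabel)
  ei <- epochFrames(plan, egtaLabel)
  ids <- colnames(R)
  nC <- ncol(R)
  rmin <- rmax <- sf <- stats::setNames(rep(NA_real_, nC), ids)
  valid <- stats::setNames(rep(FALSE, nC), ids)
  f380 <- rt@f380
  for (c in seq_len(nC)) {
    rmax[c] <- medianTopK(R[ii, c], kFrames)
    # last kFrames frames of the EGTA epoch define the free-form window
    # (earlier EGTA frames may still carry decaying calcium)
    tailIdx <- utils::tail(ei, kFrames)
    rmin[c] <- stats::median(R[tailIdx, c], na.rm = TRUE)
    # the dye is saturated for the whole ionomycin epoch, so the bound-form
    # intensity uses every frame of it; selecting frames by extreme R would
    # couple the SF estimate to the ratio noise
    sf[c] <- stats::median(f380[tailIdx, c]) / stats::median(f380[ii, c])
    valid[c] <- is.finite(rmin[c]) && is.finite(rmax[c]) &&
      is.finite(sf[c]) && rmin[c] < rmax[c] && sf[c] > 0
  }
  if (any(!valid))
    warning(sprintf("calibration invalid (rmin >= rmax or undefined) for: %s",
                    paste(ids[!valid], collapse = ", ")), call. = FALSE)
  new("CalibrationParams", kd = stats::setNames(rep(kd, nC), ids),
      sf = sf, rmin = rmin, rmax = rmax, valid = valid)
}

#' Convert 340/380 ratios to cytosolic calcium concentration (nM)
#'
#' Applies the Grynkiewicz equation per cell:
#' \deqn{[\mathrm{Ca}^{2+}]\ \mathrm{nM} = K_d \times SF \times
#'   \frac{R - R_{min}}{R_{max} - R}}
#' The conversion is strictly increasing in R on (Rmin, Rmax). Frames with
#' R >= Rmax are flagged \code{saturated_high} (concentration undefined, NA);
#' frames with R < Rmin are flagged \code{below_rmin} and clamped to 0;
#' missing ratios are flagged \code{missing}; cells with invalid calibration
#' are flagged \code{invalid_calibration} throughout.
#'
#' @param R ratio matrix from [computeRatio()].
#' @param params a [CalibrationParams-class] (cells matched by name).
#' @param times frame times in seconds (defaults to frame index).
#' @return a [CalciumConcTrace-class].
#' @examples
#' p <- new("CalibrationParams", kd = c(cell_1 = 225), sf = c(cell_1 = 2),
#'          rmin = c(cell_1 = 0.5), rmax = c(cell_1 = 5),
#'          valid = c(cell_1 = TRUE))
#' R <- matrix(1, 2, 1, dimnames = list(NULL, "cell_1"))
#' traceValues(grynkiewicz(R, p))[1, ]   # 225 * 2 * 0.5 / 4 = 56.25 nM
#' @export
grynkiewicz <- function(R, params, times = NULL) {
  stopifnot(is(params, "CalibrationParams"))
  R <- as.matrix(R)
  ids <- colnames(R)
  if (!all(ids %in% cellIds(params)))
    stop("calibration constants missing for some cells", call. = FALSE)
  conc <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  flags <- matrix("ok", nrow(R), ncol(R), dimnames = dimnames(R))
  for (c in seq_along(ids)) {
    id <- ids[c]
    if (!params@valid[[id]]) {
      flags[, c] <- "invalid_calibration"
      next
    }
    kd <- params@kd[[id]]; sf <- params@sf[[id]]
    rmin <- params@rmin[[id]]; rmax <- params@rmax[[id]]
    r <- R[, c]
    miss <- !is.finite(r)
    sat <- !miss & r >= rmax
    low <- !miss & r < rmin
    ok <- !miss & !sat & !low
    conc[ok, c] <- kd * sf * (r[ok] - rmin) / (rmax - r[ok])
    conc[low, c] <- 0
    flags[miss, c] <- "missing"
    flags[sat, c] <- "saturated_high"
    flags[low, c] <- "below_rmin"
  }
  new("CalciumConcTrace",
      times = as.numeric(times %||% (seq_len(nrow(R)) - 1L)),
      conc = conc, flags = flags)
}

#' Quantify basal calcium, store release and SOCE per cell
#'
#' From a calibrated concentration trace and the five-epoch plan:
#' \itemize{
#'   \item \code{basal_nM} — mean concentration over the basal epoch;
#'   \item \code{store_release_delta_nM} — peak concentration in the
#'     thapsigargin epoch minus basal (Ca2+ release from the ER store);
#'   \item \code{soce_delta_nM} — peak concentration in the Ca2+ add-back
#'     epoch minus basal (store-operated entry).
#' }
#' Peaks default to the plain per-epoch maximum (the stated "rise above
#' basal"); \code{robust = TRUE} uses the same median-of-top-k estimator as
#' the calibration. Flagged frames are excluded; a cell whose required epoch
#' is entirely flagged is excluded with a reason in the \code{flags} column.
#' Negative deltas are reported but flagged \code{negative_delta}.
#'
#' @param ct a [CalciumConcTrace-class].
#' @param plan an [EpochPlan-class] with \code{basal}, \code{tg} and
#'   \code{caadd} epochs.
#' @param robust use median-of-top-\code{kFrames} epoch peaks.
#' @param kFrames top-k width for robust peaks.
#' @param basalLabel,tgLabel,addbackLabel epoch labels.
#' @return data frame: \code{cell_id, basal_nM, store_release_delta_nM,
#'   soce_delta_nM, flags}.
#' @export
quantifySOCE <- function(ct, plan, robust = FALSE, kFrames = 5,
                         basalLabel = "basal", tgLabel = "tg",
                         addbackLabel = "caadd") {
  stopifnot(is(ct, "CalciumConcTrace"))
  for (lab in c(basalLabel, tgLabel, addbackLabel))
    if (!hasEpoch(plan, lab))
      stop(sprintf("SOCE quantification requires an epoch labelled '%s'", lab),
           call. = FALSE)
  bi <- epochFrames(plan, basalLabel)
  ti <- epochFrames(plan, tgLabel)
  ai <- epochFrames(plan, addbackLabel)
  peak <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    if (robust) medianTopK(x, kFrames) else max(x)
  }
  ids <- cellIds(ct)
  out <- lapply(seq_along(ids), function(c) {
    okc <- ct@flags[, c] == "ok"
    flags <- character(0)
    vals <- list(basal = ct@conc[bi, c][okc[bi]],
                 tg = ct@conc[ti, c][okc[ti]],
                 caadd = ct@conc[ai, c][okc[ai]])
    empty <- names(vals)[vapply(vals, length, integer(1)) == 0L]
    if (length(empty)) {
      return(data.frame(cell_id = ids[c], basal_nM = NA_real_,
                        store_release_delta_nM = NA_real_,
                        soce_delta_nM = NA_real_,
                        flags = paste0("excluded:all_frames_flagged_in_",
                                       paste(empty, collapse = "+")),
                        stringsAsFactors = FALSE))
    }
    basal <- mean(vals$basal)
    store <- peak(vals$tg) - basal
    soce <- peak(vals$caadd) - basal
    if (store < 0 || soce < 0) flags <- c(flags, "negative_delta")
    data.frame(cell_id = ids[c], basal_nM = basal,
               store_release_delta_nM = store, soce_delta_nM = soce,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-call SOCE analysis of a ratiometric recording
#'
#' Chains [computeRatio()], [estimateCalibration()], [grynkiewicz()] and
#' [quantifySOCE()].
#'
#' @param rt a [RatioTraceSet-class].
#' @param plan an [EpochPlan-class] (default [socePlan()]).
#' @param kd dye dissociation constant, nM.
#' @param kFrames calibration extreme-frame window.
#' @param backgroundOffset optional per-channel camera offset subtracted from
#'   both channels before any ratio (length-2 numeric: 340, 380; default 0).
#' @param ... passed to [quantifySOCE()].
#' @return list: \code{summary} (data frame), \code{conc}
#'   (a [CalciumConcTrace-class]), \code{calibration}
#'   (a [CalibrationParams-class]), \code{ratio} (matrix).
#' @export
analyzeSOCE <- function(rt, plan = socePlan(), kd = 225, kFrames = 5,
                        backgroundOffset = c(0, 0), ...) {
  stopifnot(is(rt, "RatioTraceSet"))
  if (any(backgroundOffset != 0)) {
    rt <- RatioTraceSet(rt@times, rt@f340 - backgroundOffset[1L],
                        rt@f380 - backgroundOffset[2L],
                        meta = rt@meta)
  }
  R <- computeRatio(rt)
  calib <- estimateCalibration(R, rt, plan, kd = kd, kFrames = kFrames)
  ct <- grynkiewicz(R, calib, times = rt@times)
  list(summary = quantifySOCE(ct, plan, ...), conc = ct,
       calibration = calib, ratio = R)
}
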