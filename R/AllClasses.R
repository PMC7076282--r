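#' @import methods
NULL

#' Single-wavelength fluorescence trace set
#'
#' Container for a time-lapse fluorescence recording: one column of raw
#' intensities (arbitrary units) per ROI/cell, sampled on a uniform time grid.
#' This is the raw input of the Fluo-4 transient analysis; rows are frames,
#' columns are cells.
#'
#' @slot times numeric vector of acquisition times in seconds, strictly
#'   increasing and uniformly spaced (constant frame interval \code{dt}).
#' @slot values numeric matrix, frames x cells, raw fluorescence (a.u.);
#'   column names are the cell identifiers.
#' @slot meta list of acquisition metadata: \code{dye} (character),
#'   \code{dt} (frame interval, seconds), \code{div} (culture age in days
#'   in vitro, optional) and any reader-added fields.
#'
#' @seealso [TraceSet()], [readTraceTable()], [normalizeTrace()]
#' @exportClass TraceSet
setClass("TraceSet",
  representation(times = "numeric", values = "matrix", meta = "list"))

setValidity("TraceSet", function(object) {
  msg <- character()
  v <- object@values
  t <- object@times
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (length(t) != nrow(v))
    msg <- c(msg, "length(times) must equal the number of frames (rows)")
  if (nrow(v) < 2L) msg <- c(msg, "at least 2 frames are required")
  if (ncol(v) < 1L) msg <- c(msg, "at least 1 cell is required")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "all fluorescence values must be finite")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "cell ids (column names) must be present and unique")
  if (length(t) >= 2L) {
    dts <- diff(t)
    if (any(dts <= 0)) msg <- c(msg, "'times' must be strictly increasing")
    else {
      dt <- stats::median(dts)
      if (max(abs(dts - dt)) > 1e-9 * dt)
        msg <- c(msg, "'times' must be uniformly spaced")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Two-channel (ratiometric) fluorescence trace set
#'
#' Container for a dual-excitation Fura-2 recording: per cell, one intensity
#' trace for 340 nm excitation and one for 380 nm excitation, on a shared
#' uniform time grid. Input to [computeRatio()] and the Grynkiewicz
#' calibration.
#'
#' @slot times numeric, seconds, uniform spacing.
#' @slot f340 numeric matrix frames x cells, 340 nm-excitation emission (a.u.).
#' @slot f380 numeric matrix frames x cells, 380 nm-excitation emission (a.u.);
#'   same shape and column names as \code{f340}. Non-positive F380 frames are
#'   permitted in the container but are flagged and excluded from ratios.
#' @slot meta list of acquisition metadata (as for [TraceSet-class]).
#'
#' @seealso [RatioTraceSet()], [readRatioTable()], [computeRatio()]
#' @exportClass RatioTraceSet
setClass("RatioTraceSet",
  representation(times = "numeric", f340 = "matrix", f380 = "matrix",
                 meta = "list"))

setValidity("RatioTraceSet", function(object) {
  msg <- character()
  if (!identical(dim(object@f340), dim(object@f380)))
    msg <- c(msg, "f340 and f380 must have identical dimensions")
  if (!identical(colnames(object@f340), colnames(object@f380)))
    msg <- c(msg, "f340 and f380 must have identical cell ids")
  if (length(object@times) != nrow(object@f340))
    msg <- c(msg, "length(times) must equal the number of frames")
  if (anyNA(object@f340) || any(!is.finite(object@f340)) ||
      anyNA(object@f380) || any(!is.finite(object@f380)))
    msg <- c(msg, "all channel values must be finite")
  if (is.null(colnames(object@f340)) || anyDuplicated(colnames(object@f340)))
    msg <- c(msg, "cell ids (column names) must be present and unique")
  if (length(object@times) >= 2L) {
    dts <- diff(object@times)
    if (any(dts <= 0)) msg <- c(msg, "'times' must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Epoch plan: labelled treatment intervals of a recording
#'
#' An ordered set of non-overlapping, labelled frame intervals segmenting a
#' recording into its protocol phases (e.g. baseline, TTX, thapsigargin,
#' Ca2+ add-back, ionomycin, EGTA). Frame indices are 0-based and half-open:
#' an epoch \code{[start, end)} covers frames \code{start} to \code{end - 1}.
#'
#' @slot label character, unique epoch labels, in temporal order.
#' @slot start integer, inclusive 0-based start frame per epoch.
#' @slot end integer, exclusive end frame per epoch.
#' @slot treatment character, free-text treatment annotation per epoch.
#'
#' @seealso [epochPlan()], [socePlan()], [fluo4Plan()], [readEpochPlan()]
#' @exportClass EpochPlan
setClass("EpochPlan",
  representation(label = "character", start = "integer", end = "integer",
                 treatment = "character"))

setValidity("EpochPlan", function(object) {
  msg <- character()
  n <- length(object@label)
  if (length(object@start) != n || length(object@end) != n ||
      length(object@treatment) != n)
    msg <- c(msg, "label, start, end, treatment must have equal length")
  if (n == 0L) msg <- c(msg, "at least one epoch is required")
  if (anyDuplicated(object@label)) msg <- c(msg, "epoch labels must be unique")
  if (n > 0L && length(msg) == 0L) {
    if (any(object@start < 0L)) msg <- c(msg, "start frames must be >= 0")
    if (any(object@end <= object@start))
      msg <- c(msg, sprintf("epoch '%s' has end <= start",
                            object@label[which(object@end <= object@start)[1L]]))
    if (n > 1L) {
      bad <- which(object@start[-1L] < object@end[-n])
      if (length(bad))
        msg <- c(msg, sprintf("epochs '%s' and '%s' overlap or are out of order",
                              object@label[bad[1L]], object@label[bad[1L] + 1L]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Normalized fluorescence traces (F/F0 and dF/F0)
#'
#' Result of [normalizeTrace()]: per cell, raw intensity divided by the
#' intensity at a reference baseline frame (\code{norm} = F/F0, equal to 1 at
#' the reference frame) and the corresponding relative change
#' \code{dff} = F/F0 - 1.
#'
#' @slot times numeric, seconds.
#' @slot norm numeric matrix frames x cells, F/F0 (dimensionless).
#' @slot dff numeric matrix, dF/F0 = norm - 1.
#' @slot f0 named numeric, per-cell reference intensity (a.u.).
#' @slot refFrame integer, 0-based index of the reference frame.
#' @slot excluded named character: cells dropped during normalization
#'   (e.g. non-positive reference intensity), value is the reason.
#'
#' @seealso [normalizeTrace()], [firstDerivative()], [detectEvents()]
#' @exportClass NormalizedTrace
setClass("NormalizedTrace",
  representation(times = "numeric", norm = "matrix", dff = "matrix",
                 f0 = "numeric", refFrame = "integer", excluded = "character"))

setValidity("NormalizedTrace", function(object) {
  msg <- character()
  if (!identical(dim(object@norm), dim(object@dff)))
    msg <- c(msg, "norm and dff must have identical dimensions")
  if (length(object@f0) != ncol(object@norm))
    msg <- c(msg, "f0 must have one value per cell")
  if (object@refFrame < 0L || object@refFrame >= nrow(object@norm))
    msg <- c(msg, "refFrame out of range")
  else {
    if (max(abs(object@norm[object@refFrame + 1L, ] - 1)) > 1e-12)
      msg <- c(msg, "norm at the reference frame must equal 1 for every cell")
    if (max(abs(object@dff - (object@norm - 1))) > 1e-12)
      msg <- c(msg, "dff must equal norm - 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell Fura-2 calibration constants
#'
#' Holds the constants of the Grynkiewicz conversion for each cell: the dye
#' dissociation constant Kd (nM), the per-cell scaling factor SF (ratio of
#' Ca2+-free to Ca2+-bound 380 nm emission), and the ratio extremes Rmin
#' (Ca2+-free, EGTA) and Rmax (Ca2+-saturated, ionomycin).
#'
#' @slot kd numeric, nM, per cell (usually a shared constant, default 225).
#' @slot sf numeric, dimensionless, per cell, > 0.
#' @slot rmin numeric, per cell.
#' @slot rmax numeric, per cell; \code{rmin < rmax} required for validity.
#' @slot valid logical, per cell: FALSE marks cells whose calibration failed
#'   (e.g. rmin >= rmax); such cells are flagged, never silently dropped.
#'
#' @seealso [estimateCalibration()], [grynkiewicz()]
#' @exportClass CalibrationParams
setClass("CalibrationParams",
  representation(kd = "numeric", sf = "numeric", rmin = "numeric",
                 rmax = "numeric", valid = "logical"))

setValidity("CalibrationParams", function(object) {
  msg <- character()
  n <- length(object@kd)
  if (length(object@sf) != n || length(object@rmin) != n ||
      length(object@rmax) != n || length(object@valid) != n)
    msg <- c(msg, "all slots must have one value per cell")
  if (is.null(names(object@kd))) msg <- c(msg, "cell ids (names) are required")
  if (any(object@kd <= 0, na.rm = TRUE)) msg <- c(msg, "kd must be > 0")
  ok <- object@valid
  if (any(ok & !(object@sf > 0), na.rm = TRUE))
    msg <- c(msg, "sf must be > 0 for valid cells")
  if (any(ok & !(object@rmin < object@rmax), na.rm = TRUE))
    msg <- c(msg, "rmin < rmax required for valid cells")
  if (length(msg)) msg else TRUE
})

#' Cytosolic calcium concentration traces (nM)
#'
#' Per-frame, per-cell [Ca2+]i estimates from the Grynkiewicz conversion,
#' with quality flags: \code{"ok"}, \code{"saturated_high"} (R >= Rmax,
#' concentration undefined), \code{"below_rmin"} (R < Rmin, clamped to 0),
#' \code{"missing"} (ratio unavailable, e.g. non-positive F380), or
#' \code{"invalid_calibration"} for cells without usable constants.
#'
#' @slot times numeric, seconds.
#' @slot conc numeric matrix frames x cells, nM; NA where flagged undefined.
#' @slot flags character matrix, same shape, quality code per entry.
#'
#' @seealso [grynkiewicz()], [quantifySOCE()]
#' @exportClass CalciumConcTrace
setClass("CalciumConcTrace",
  representation(times = "numeric", conc = "matrix", flags = "matrix"))

setValidity("CalciumConcTrace", function(object) {
  msg <- character()
  if (!identical(dim(object@conc), dim(object@flags)))
    msg <- c(msg, "conc and flags must have identical dimensions")
  if (length(object@times) != nrow(object@conc))
    msg <- c(msg, "length(times) must equal the number of frames")
  ok <- object@flags == "ok"
  if (any(ok & (!is.finite(object@conc) | object@conc < 0)))
    msg <- c(msg, "unflagged concentrations must be finite and >= 0")
  if (length(msg)) msg else TRUE
})
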