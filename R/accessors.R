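#' Accessors for trace containers
#'
#' @param x a trace container ([TraceSet-class], [RatioTraceSet-class],
#'   [NormalizedTrace-class] or [CalciumConcTrace-class]).
#' @return \code{nFrames}/\code{nCells}: integer counts; \code{cellIds}:
#'   character vector; \code{traceTimes}: numeric seconds;
#'   \code{traceValues}: the frames x cells value matrix (raw F for a
#'   \code{TraceSet}, concentration for a \code{CalciumConcTrace});
#'   \code{frameInterval}: the frame interval dt in seconds;
#'   \code{traceMeta}: the metadata list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("nFrames", "TraceSet", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nFrames", "RatioTraceSet", function(x) nrow(x@f340))
#' @rdname accessors
#' @export
setMethod("nFrames", "NormalizedTrace", function(x) nrow(x@norm))
#' @rdname accessors
#' @export
setMethod("nFrames", "CalciumConcTrace", function(x) nrow(x@conc))

#' @rdname accessors
#' @export
setMethod("nCells", "TraceSet", function(x) ncol(x@values))
#' @rdname accessors
#' @export
setMethod("nCells", "RatioTraceSet", function(x) ncol(x@f340))
#' @rdname accessors
#' @export
setMethod("nCells", "NormalizedTrace", function(x) ncol(x@norm))
#' @rdname accessors
#' @export
setMethod("nCells", "CalciumConcTrace", function(x) ncol(x@conc))

#' @rdname accessors
#' @export
setMethod("cellIds", "TraceSet", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("cellIds", "RatioTraceSet", function(x) colnames(x@f340))
#' @rdname accessors
#' @export
setMethod("cellIds", "NormalizedTrace", function(x) colnames(x@norm))
#' @rdname accessors
#' @export
setMethod("cellIds", "CalciumConcTrace", function(x) colnames(x@conc))
#' @rdname accessors
#' @export
setMethod("cellIds", "CalibrationParams", function(x) names(x@kd))

#' @rdname accessors
#' @export
setMethod("traceTimes", "TraceSet", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("traceTimes", "RatioTraceSet", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("traceTimes", "NormalizedTrace", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("traceTimes", "CalciumConcTrace", function(x) x@times)

#' @rdname accessors
#' @export
setMethod("traceValues", "TraceSet", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("traceValues", "CalciumConcTrace", function(x) x@conc)

#' @rdname accessors
#' @export
setMethod("frameInterval", "TraceSet", function(x) stats::median(diff(x@times)))
#' @rdname accessors
#' @export
setMethod("frameInterval", "RatioTraceSet",
          function(x) stats::median(diff(x@times)))

#' @rdname accessors
#' @export
setMethod("traceMeta", "TraceSet", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("traceMeta", "RatioTraceSet", function(x) x@meta)

#' Channel accessors for ratiometric trace sets
#'
#' @param x a [RatioTraceSet-class].
#' @return numeric matrix frames x cells for the requested excitation channel.
#' @export
f340 <- function(x) {
  stopifnot(is(x, "RatioTraceSet"))
  x@f340
}

#' @rdname f340
#' @export
f380 <- function(x) {
  stopifnot(is(x, "RatioTraceSet"))
  x@f380
}

#' Matrix accessors for normalized traces
#'
#' @param x a [NormalizedTrace-class].
#' @return \code{normValues}: F/F0 matrix; \code{dffValues}: dF/F0 matrix;
#'   \code{f0Values}: named per-cell reference intensities;
#'   \code{excludedCells}: named character vector of dropped cells (reasons).
#' @export
normValues <- function(x) {
  stopifnot(is(x, "NormalizedTrace"))
  x@norm
}

#' @rdname normValues
#' @export
dffValues <- function(x) {
  stopifnot(is(x, "NormalizedTrace"))
  x@dff
}

#' @rdname normValues
#' @export
f0Values <- function(x) {
  stopifnot(is(x, "NormalizedTrace"))
  x@f0
}

#' @rdname normValues
#' @export
excludedCells <- function(x) {
  stopifnot(is(x, "NormalizedTrace"))
  x@excluded
}

#' Quality flags of a concentration trace
#'
#' @param x a [CalciumConcTrace-class].
#' @return character matrix of per-frame, per-cell quality codes.
#' @export
concFlags <- function(x) {
  stopifnot(is(x, "CalciumConcTrace"))
  x@flags
}

#' Calibration constant accessors
#'
#' @param x a [CalibrationParams-class].
#' @return named numeric (or logical for \code{calibValid}) vector, one entry
#'   per cell.
#' @export
calibKd <- function(x) {
  stopifnot(is(x, "CalibrationParams"))
  x@kd
}

#' @rdname calibKd
#' @export
calibSf <- function(x) {
  stopifnot(is(x, "CalibrationParams"))
  x@sf
}

#' @rdname calibKd
#' @export
calibRmin <- function(x) {
  stopifnot(is(x, "CalibrationParams"))
  x@rmin
}

#' @rdname calibKd
#' @export
calibRmax <- function(x) {
  stopifnot(is(x, "CalibrationParams"))
  x@rmax
}

#' @rdname calibKd
#' @export
calibValid <- function(x) {
  stopifnot(is(x, "CalibrationParams"))
  x@valid
}

setMethod("show", "TraceSet", function(object) {
  cat(sprintf("TraceSet: %d frames x %d cells, dt = %g s (%s)\n",
              nFrames(object), nCells(object), frameInterval(object),
              object@meta$dye %||% "unknown dye"))
  cat(sprintf("  time range: [%g, %g] s\n",
              object@times[1L], object@times[length(object@times)]))
})

setMethod("show", "RatioTraceSet", function(object) {
  cat(sprintf("RatioTraceSet: %d frames x %d cells, dt = %g s (340/380 nm)\n",
              nFrames(object), nCells(object), frameInterval(object)))
})

setMethod("show", "EpochPlan", function(object) {
  cat(sprintf("EpochPlan: %d epochs, frames [%d, %d)\n",
              length(object@label), min(object@start), max(object@end)))
  df <- as.data.frame(object)
  print(df, row.names = FALSE)
})

setMethod("show", "NormalizedTrace", function(object) {
  cat(sprintf(
    "NormalizedTrace: %d frames x %d cells, reference frame %d (0-based)\n",
    nFrames(object), nCells(object), object@refFrame))
  if (length(object@excluded))
    cat(sprintf("  excluded cells: %s\n",
                paste(names(object@excluded), collapse = ", ")))
})

setMethod("show", "CalibrationParams", function(object) {
  cat(sprintf("CalibrationParams: %d cells (%d valid), Kd median %g nM\n",
              length(object@kd), sum(object@valid),
              stats::median(object@kd)))
})

setMethod("show", "CalciumConcTrace", function(object) {
  pct <- 100 * mean(object@flags != "ok")
  cat(sprintf("CalciumConcTrace: %d frames x %d cells, %.1f%% frames flagged\n",
              nFrames(object), nCells(object), pct))
})
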