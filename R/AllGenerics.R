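#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("traceMeta", function(x) standardGeneric("traceMeta"))

#' Compute the frame-to-frame first derivative of normalized traces
#'
#' @param x a [NormalizedTrace-class] (or a plain numeric matrix of
#'   frames x cells values).
#' @param ... unused.
#' @return numeric matrix of (frames - 1) rows: row t (1-based) holds
#'   \code{dff[t + 1, ] - dff[t, ]}, i.e. the change landing on frame t in
#'   0-based frame numbering. Raw finite differences, no smoothing.
#' @export
setGeneric("firstDerivative", function(x, ...) standardGeneric("firstDerivative"))
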