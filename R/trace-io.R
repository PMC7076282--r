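#' Construct trace containers
#'
#' \code{TraceSet} wraps a frames x cells fluorescence matrix and its time
#' grid; \code{RatioTraceSet} wraps the two excitation channels of a
#' ratiometric recording. Column names are taken as cell ids (generated as
#' \code{cell_1 ...} if absent).
#'
#' @param times numeric, seconds, uniform grid.
#' @param values numeric matrix frames x cells (raw fluorescence, a.u.).
#' @param dye indicator name recorded in the metadata.
#' @param div optional culture age (days in vitro).
#' @param meta additional metadata entries (list).
#' @return a [TraceSet-class] or [RatioTraceSet-class].
#' @export
TraceSet <- function(times, values, dye = "Fluo-4", div = NA_real_,
                     meta = list()) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cell_", seq_len(ncol(values)))
  meta <- utils::modifyList(
    list(dye = dye, dt = stats::median(diff(times)), div = div), meta)
  new("TraceSet", times = as.numeric(times), values = values, meta = meta)
}

#' @rdname TraceSet
#' @param f340,f380 numeric matrices frames x cells, emission under 340 nm
#'   and 380 nm excitation.
#' @export
RatioTraceSet <- function(times, f340, f380, dye = "Fura-2", div = NA_real_,
                          meta = list()) {
  f340 <- as.matrix(f340)
  f380 <- as.matrix(f380)
  if (is.null(colnames(f340)))
    colnames(f340) <- paste0("cell_", seq_len(ncol(f340)))
  if (is.null(colnames(f380))) colnames(f380) <- colnames(f340)
  meta <- utils::modifyList(
    list(dye = dye, dt = stats::median(diff(times)), div = div), meta)
  obj <- new("RatioTraceSet", times = as.numeric(times), f340 = f340,
             f380 = f380, meta = meta)
  nonpos <- colSums(f380 <= 0)
  if (any(nonpos > 0)) {
    bad <- nonpos[nonpos > 0]
    warning(sprintf(
      "non-positive F380 frames flagged (excluded from ratios): %s",
      paste(sprintf("%s (%d)", names(bad), bad), collapse = ", ")),
      call. = FALSE)
    obj@meta$f380_nonpositive <- bad
  }
  obj
}

# read a delimiter-separated table, skipping '#' comment lines, and check
# every payload cell parses as a number (reporting row/column on failure)
readNumericTable <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("trace table needs a time column plus at least one ROI column",
         call. = FALSE)
  num <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)))
  bad <- which(is.na(num) & !is.na(df), arr.ind = TRUE)
  if (nrow(df) && length(bad) && nrow(bad))
    stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                 as.matrix(df)[bad[1L, 1L], bad[1L, 2L]],
                 bad[1L, 1L], names(df)[bad[1L, 2L]]), call. = FALSE)
  num
}

# validate uniform sampling of raw timestamps (jitter tolerance relative to
# the median interval) and return the regularized uniform grid
regularizeTimes <- function(times, tol = 1e-6) {
  if (length(times) < 2L) stop("at least 2 frames are required", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0))
    stop(sprintf("non-increasing time stamps at frame %d",
                 which(dts <= 0)[1L] - 1L), call. = FALSE)
  dt <- stats::median(dts)
  off <- abs(dts - dt)
  if (max(off) > tol * dt) {
    i <- which.max(off)
    stop(sprintf(
      "non-uniform sampling: interval between frames %d and %d is %g s (median %g s)",
      i - 1L, i, dts[i], dt), call. = FALSE)
  }
  times[1L] + dt * (seq_along(times) - 1L)
}

#' Read a wide trace table
#'
#' Reads a delimiter-separated, UTF-8 text export of an ROI time-lapse: a
#' header row, first column \code{time_s} (seconds), one column per ROI/cell
#' (raw fluorescence, a.u.). Lines starting with \code{#} are ignored.
#' Timestamps must be uniform within \code{tol} relative jitter and are
#' regularized onto the exact median-interval grid.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @param dye,div metadata passed to [TraceSet()].
#' @param tol relative sampling-jitter tolerance.
#' @return a [TraceSet-class]; column order is preserved as cell order.
#' @export
readTraceTable <- function(path, sep = "\t", dye = "Fluo-4", div = NA_real_,
                           tol = 1e-6) {
  num <- readNumericTable(path, sep = sep)
  times <- regularizeTimes(num[, 1L], tol = tol)
  values <- num[, -1L, drop = FALSE]
  TraceSet(times, values, dye = dye, div = div,
           meta = list(source = path))
}

#' @rdname readTraceTable
#' @param x a [TraceSet-class] to write.
#' @param path output path.
#' @export
writeTraceTable <- function(x, path, sep = "\t") {
  stopifnot(is(x, "TraceSet"))
  df <- cbind(time_s = x@times, as.data.frame(x@values))
  writeResultTable(df, path, kind = "trace", sep = sep)
}

#' Read a two-channel ratiometric recording
#'
#' Either two wide tables (one per excitation channel, same layout as
#' [readTraceTable()]) or a single long-format file with columns
#' \code{time_s, cell_id, f340, f380}. The two channels must share times and
#' shape; cells with non-positive F380 frames are flagged in the metadata
#' (and excluded from ratios downstream), never silently dropped.
#'
#' @param path340 wide table of the 340 nm channel, or the long-format file
#'   when \code{path380} is NULL.
#' @param path380 wide table of the 380 nm channel (or NULL).
#' @param sep field delimiter.
#' @param div culture age metadata.
#' @param tol relative sampling-jitter tolerance.
#' @return a [RatioTraceSet-class].
#' @export
readRatioTable <- function(path340, path380 = NULL, sep = "\t",
                           div = NA_real_, tol = 1e-6) {
  if (is.null(path380)) return(readRatioTableLong(path340, sep = sep,
                                                  div = div, tol = tol))
  a <- readNumericTable(path340, sep = sep)
  b <- readNumericTable(path380, sep = sep)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("channel shape mismatch: %d x %d vs %d x %d",
                 nrow(a), ncol(a) - 1L, nrow(b), ncol(b) - 1L), call. = FALSE)
  if (max(abs(a[, 1L] - b[, 1L])) > tol * stats::median(diff(a[, 1L])))
    stop("channel time stamps differ", call. = FALSE)
  if (!identical(colnames(a), colnames(b)))
    stop("channel cell ids differ", call. = FALSE)
  times <- regularizeTimes(a[, 1L], tol = tol)
  RatioTraceSet(times, a[, -1L, drop = FALSE], b[, -1L, drop = FALSE],
                div = div, meta = list(source = c(path340, path380)))
}

readRatioTableLong <- function(path, sep = "\t", div = NA_real_, tol = 1e-6) {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("time_s", "cell_id", "f340", "f380")
  if (!all(need %in% names(df)))
    stop(sprintf("long-format ratio table needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  cells <- unique(df$cell_id)
  times <- sort(unique(df$time_s))
  a <- b <- matrix(NA_real_, length(times), length(cells),
                   dimnames = list(NULL, cells))
  ri <- match(df$time_s, times)
  ci <- match(df$cell_id, cells)
  a[cbind(ri, ci)] <- df$f340
  b[cbind(ri, ci)] <- df$f380
  if (anyNA(a) || anyNA(b))
    stop("long-format ratio table is not a complete time x cell grid",
         call. = FALSE)
  RatioTraceSet(regularizeTimes(times, tol = tol), a, b, div = div,
                meta = list(source = path))
}

#' @rdname readRatioTable
#' @param x a [RatioTraceSet-class] to write (one file per channel).
#' @export
writeRatioTable <- function(x, path340, path380, sep = "\t") {
  stopifnot(is(x, "RatioTraceSet"))
  writeResultTable(cbind(time_s = x@times, as.data.frame(x@f340)), path340,
                   kind = "trace_f340", sep = sep)
  writeResultTable(cbind(time_s = x@times, as.data.frame(x@f380)), path380,
                   kind = "trace_f380", sep = sep)
  invisible(c(path340, path380))
}

#' Write / read result tables
#'
#' All result tables are UTF-8 delimiter-separated text with a schema header
#' comment line (\code{# neurocal-table v1 kind=<kind>}) followed by a header
#' row. Numeric columns are written at full precision (\code{\%.17g}), so the
#' matching reader round-trips finite doubles bit-exactly. Column order is
#' deterministic (as in the data frame).
#'
#' @param df a data frame (may have zero rows: header-only file).
#' @param path output path.
#' @param kind short schema tag recorded in the header comment.
#' @param sep field delimiter.
#' @return the path (writer, invisibly) or the data frame (reader), with the
#'   schema tag in attribute \code{"kind"}.
#' @export
writeResultTable <- function(df, path, kind = "table", sep = "\t") {
  if (!is.data.frame(df) || ncol(df) == 0L)
    stop("'df' must be a data frame with at least one column", call. = FALSE)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e)
                    stop(sprintf("cannot write '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  on.exit(close(con))
  writeLines(sprintf("# neurocal-table v1 kind=%s", kind), con)
  out <- as.data.frame(lapply(df, fullPrecision), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  kind <- sub("^# neurocal-table v1 kind=", "", first)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "kind") <- if (startsWith(first, "#")) kind else NA_character_
  df
}
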