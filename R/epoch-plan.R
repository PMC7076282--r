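#' Construct an epoch plan
#'
#' Builds an [EpochPlan-class] from labelled frame intervals. Frame indices
#' are 0-based and half-open: epoch \code{[start, end)} covers frames
#' \code{start .. end - 1}. Epochs must be ordered and non-overlapping; with
#' \code{strict = TRUE} they must also be contiguous (no gaps).
#'
#' @param label character, unique epoch labels in temporal order.
#' @param start integer, inclusive 0-based start frames.
#' @param end integer, exclusive end frames.
#' @param treatment character, treatment annotation per epoch (recycled).
#' @param nFrames optional recording length; epochs beyond it are an error.
#' @param strict logical; require contiguous epochs.
#' @return an [EpochPlan-class].
#' @examples
#' epochPlan(c("baseline", "ttx"), c(0, 240), c(240, 480),
#'           c("none", "TTX 1 uM"))
#' @export
epochPlan <- function(label, start, end, treatment = "none",
                      nFrames = NULL, strict = FALSE) {
  n <- length(label)
  treatment <- rep_len(as.character(treatment), n)
  start <- unname(vapply(start, assertCount, integer(1), name = "start",
                         positive = FALSE))
  end <- unname(vapply(end, assertCount, integer(1), name = "end",
                       positive = FALSE))
  if (n > 1L) {
    bad <- which(start[-1L] < end[-n])
    if (length(bad))
      stop(sprintf("epochs '%s' and '%s' overlap or are out of order",
                   label[bad[1L]], label[bad[1L] + 1L]), call. = FALSE)
    if (strict) {
      gap <- which(start[-1L] != end[-n])
      if (length(gap))
        stop(sprintf("gap between epochs '%s' and '%s' (strict mode)",
                     label[gap[1L]], label[gap[1L] + 1L]), call. = FALSE)
    }
  }
  if (!is.null(nFrames)) {
    over <- which(end > nFrames)
    if (length(over))
      stop(sprintf("epoch '%s' extends beyond the recording (%d frames)",
                   label[over[1L]], nFrames), call. = FALSE)
  }
  new("EpochPlan", label = as.character(label), start = start, end = end,
      treatment = treatment)
}

#' @describeIn epochPlan Preset plan for the five-epoch Fura-2 SOCE protocol:
#'   basal in zero-Ca buffer (12 frames), thapsigargin store depletion
#'   (84 frames), 2 mM Ca2+ add-back revealing SOCE (60 frames), ionomycin
#'   saturation (24 frames) and EGTA chelation (24 frames), at 5 s per frame
#'   (204 frames = 17 min).
#' @param dt frame interval in seconds (used only for documentation of the
#'   preset; the plan itself is in frames).
#' @export
socePlan <- function(dt = 5) {
  lens <- c(basal = 12L, tg = 84L, caadd = 60L, iono = 24L, egta = 24L)
  ends <- cumsum(lens)
  epochPlan(label = names(lens), start = c(0L, ends[-5L]), end = ends,
            treatment = c("zero Ca2+ HBSS", "thapsigargin 10 uM",
                          "CaCl2 2 mM add-back", "ionomycin 20 uM",
                          "EGTA 4 mM"),
            strict = TRUE)
}

#' @describeIn epochPlan Preset plan for the Fluo-4 spontaneous-transient
#'   protocol: a 4-minute baseline followed by a 4-minute activity-abolishing
#'   treatment epoch, at \code{dt} seconds per frame (default 1 s).
#' @param treatmentLabel label of the second epoch (default \code{"ttx"}).
#' @export
fluo4Plan <- function(dt = 1, treatmentLabel = "ttx") {
  b <- as.integer(round(240 / dt))
  epochPlan(label = c("baseline", treatmentLabel),
            start = c(0L, b), end = c(b, 2L * b),
            treatment = c("none", "TTX"), strict = TRUE)
}

#' Read an epoch plan from a YAML configuration
#'
#' The file holds a top-level \code{epochs} list; each entry names a
#' \code{label}, optional \code{treatment}, and either \code{frames:
#' [start, end)} (0-based half-open) or \code{duration_s} (converted with the
#' top-level \code{dt}). Durations are laid out contiguously in order.
#'
#' @param path path to the YAML file.
#' @param strict logical; require contiguous epochs.
#' @return an [EpochPlan-class].
#' @export
readEpochPlan <- function(path, strict = FALSE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$epochs)) stop("epoch plan must contain an 'epochs' list")
  dt <- cfg$dt %||% 1
  cursor <- 0L
  lab <- trt <- character(0)
  s <- e <- integer(0)
  for (ep in cfg$epochs) {
    if (is.null(ep$label)) stop("every epoch needs a 'label'")
    lab <- c(lab, ep$label)
    trt <- c(trt, ep$treatment %||% "none")
    if (!is.null(ep$frames)) {
      if (length(ep$frames) != 2L)
        stop(sprintf("epoch '%s': 'frames' must be [start, end)", ep$label))
      s <- c(s, as.integer(ep$frames[[1L]]))
      e <- c(e, as.integer(ep$frames[[2L]]))
      cursor <- as.integer(ep$frames[[2L]])
    } else if (!is.null(ep$duration_s)) {
      k <- ep$duration_s / dt
      if (abs(k - round(k)) > 1e-9)
        stop(sprintf("epoch '%s': duration_s is not a multiple of dt", ep$label))
      s <- c(s, cursor)
      e <- c(e, cursor + as.integer(round(k)))
      cursor <- cursor + as.integer(round(k))
    } else {
      stop(sprintf("epoch '%s' needs 'frames' or 'duration_s'", ep$label))
    }
  }
  epochPlan(lab, s, e, trt, strict = strict)
}

#' Write an epoch plan to YAML
#'
#' @param plan an [EpochPlan-class].
#' @param path output path.
#' @param dt frame interval recorded in the file, seconds.
#' @return the path, invisibly.
#' @export
writeEpochPlan <- function(plan, path, dt = 1) {
  eps <- lapply(seq_along(plan@label), function(i) {
    list(label = plan@label[i], treatment = plan@treatment[i],
         frames = c(plan@start[i], plan@end[i]))
  })
  yaml::write_yaml(list(dt = dt, epochs = eps), path)
  invisible(path)
}

#' Epoch plan utilities
#'
#' \code{epochWindow} returns the 0-based half-open \code{c(start, end)} of
#' one epoch; \code{epochFrames} the corresponding 1-based R row indices;
#' \code{epochLabels} all labels; \code{hasEpoch} tests membership.
#'
#' @param plan an [EpochPlan-class].
#' @param label an epoch label.
#' @return see description.
#' @export
epochWindow <- function(plan, label) {
  i <- match(label, plan@label)
  if (is.na(i)) stop(sprintf("no epoch labelled '%s' in the plan", label),
                     call. = FALSE)
  c(start = unname(plan@start[i]), end = unname(plan@end[i]))
}

#' @rdname epochWindow
#' @export
epochFrames <- function(plan, label) {
  w <- epochWindow(plan, label)
  seq.int(w[["start"]] + 1L, w[["end"]])
}

#' @rdname epochWindow
#' @export
epochLabels <- function(plan) plan@label

#' @rdname epochWindow
#' @export
hasEpoch <- function(plan, label) label %in% plan@label

#' @export
#' @method as.data.frame EpochPlan
as.data.frame.EpochPlan <- function(x, ...) {
  data.frame(label = x@label, start_frame = x@start, end_frame = x@end,
             treatment = x@treatment, stringsAsFactors = FALSE)
}

setMethod("nFrames", "EpochPlan", function(x) max(x@end))
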