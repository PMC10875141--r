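#' @rdname SessionSchedule-class
#' @param object,x an object.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname SessionSchedule-class
#' @export
setGeneric("csOnsets", function(object) standardGeneric("csOnsets"))

#' @rdname SessionSchedule-class
#' @export
setGeneric("sessionDuration", function(object) standardGeneric("sessionDuration"))

#' Sampling rate accessor
#' @param object an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Derive labelled epoch windows from a schedule
#'
#' @param schedule a [SessionSchedule-class] object.
#' @param family which window family to derive: \code{"behavior"} (baseline,
#'   tone, trace, shock, iti per trial), \code{"photometry"} (pre_shock and
#'   post_shock per trial) or \code{"swr"} (swr_baseline once, swr_iti per
#'   trial).
#' @param ... passed to methods.
#' @return a data.frame with columns \code{label}, \code{start}, \code{end}
#'   (seconds, half-open \code{[start, end)}) and \code{trial_index}
#'   (0-based trial number, \code{NA} for session-level windows).
#' @export
setGeneric("epochWindows", function(schedule, family = c("behavior", "photometry", "swr"), ...) {
  standardGeneric("epochWindows")
})

#' Downsample a photometry session by non-overlapping bin means
#' @param session a [PhotometrySession-class].
#' @param targetFs target sampling rate in Hz; must divide \code{fs} exactly.
#' @export
setGeneric("downsampleSession", function(session, targetFs) {
  standardGeneric("downsampleSession")
})

#' @rdname TrialMatrix-class
#' @export
setGeneric("isZscored", function(object) standardGeneric("isZscored"))
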