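#' @import methods
NULL

#' Trace-fear-conditioning session schedule
#'
#' Represents the temporal structure of a trace-fear-conditioning (TFC)
#' session: an initial baseline period followed by \code{nTrials} identical
#' trials, each consisting of a tone (CS), a stimulus-free trace interval,
#' a footshock (US) and an intertrial interval (ITI). All times are seconds
#' from session start; all intervals derived from a schedule are half-open
#' \code{[start, end)} so a sample on a boundary belongs to exactly one epoch.
#'
#' @slot baselineDuration seconds of baseline before the first tone.
#' @slot nTrials number of conditioning trials.
#' @slot toneDuration,traceDuration,shockDuration,itiDuration per-trial epoch
#'   durations in seconds.
#' @slot csOnsets absolute CS (tone) onset times in seconds; strictly
#'   increasing, first onset equals \code{baselineDuration}, consecutive onsets
#'   separated by tone + trace + shock + ITI.
#'
#' @seealso [buildSchedule()], [epochWindows()]
#' @export
setClass("SessionSchedule",
  representation(
    baselineDuration = "numeric",
    nTrials = "integer",
    toneDuration = "numeric",
    traceDuration = "numeric",
    shockDuration = "numeric",
    itiDuration = "numeric",
    csOnsets = "numeric"
  )
)

setValidity("SessionSchedule", function(object) {
  msg <- character()
  durs <- c(
    baseline = object@baselineDuration, tone = object@toneDuration,
    trace = object@traceDuration, shock = object@shockDuration,
    iti = object@itiDuration
  )
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    msg <- c(msg, "all durations must be finite and strictly positive")
  }
  if (length(object@nTrials) != 1L || is.na(object@nTrials) ||
      object@nTrials < 1L) {
    msg <- c(msg, "nTrials must be a single integer >= 1")
  }
  if (object@shockDuration >= object@traceDuration) {
    msg <- c(msg, "shockDuration must be smaller than traceDuration")
  }
  on <- object@csOnsets
  if (length(on) != object@nTrials) {
    msg <- c(msg, "csOnsets length must equal nTrials")
  } else {
    if (any(diff(on) <= 0)) msg <- c(msg, "csOnsets must be strictly increasing")
    if (abs(on[1] - object@baselineDuration) > 1e-9) {
      msg <- c(msg, "first CS onset must equal baselineDuration")
    }
    period <- object@toneDuration + object@traceDuration +
      object@shockDuration + object@itiDuration
    if (length(on) > 1 && any(abs(diff(on) - period) > 1e-9)) {
      msg <- c(msg, "consecutive CS onsets must differ by tone+trace+shock+iti")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Two-channel fiber-photometry session
#'
#' Paired 465 nm (calcium-dependent GCaMP) and 405 nm (isosbestic,
#' calcium-independent) fluorescence time series on a common uniform time
#' grid, with TTL-derived event times for synchronisation.
#'
#' @slot time sample times in seconds (uniform spacing \code{1/fs}).
#' @slot signal465 465 nm fluorescence, arbitrary units.
#' @slot control405 405 nm isosbestic fluorescence, arbitrary units.
#' @slot fs sampling rate in Hz.
#' @slot ttlEvents named list mapping an event label to a numeric vector of
#'   event times in seconds.
#'
#' @export
setClass("PhotometrySession",
  representation(
    time = "numeric",
    signal465 = "numeric",
    control405 = "numeric",
    fs = "numeric",
    ttlEvents = "list"
  )
)

setValidity("PhotometrySession", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@signal465) != n || length(object@control405) != n) {
    msg <- c(msg, "time, signal465 and control405 must have equal length")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (n > 1 && length(object@fs) == 1L && is.finite(object@fs)) {
    if (max(abs(diff(object@time) - 1 / object@fs)) > 1e-6) {
      msg <- c(msg, "time must be uniformly spaced at 1/fs (tolerance 1e-6)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Isosbestic-corrected dF/F trace
#'
#' Percent dF/F obtained by regressing the 465 nm signal on the 405 nm
#' control over the whole session and normalising the actual 465 nm signal
#' by the predicted one: \code{dF/F = (actual - predicted)/predicted * 100}.
#'
#' @slot time seconds.
#' @slot dff percent dF/F.
#' @slot fs Hz.
#' @slot fitSlope,fitIntercept coefficients of the ordinary-least-squares fit
#'   predicting the 465 nm signal from the 405 nm signal.
#'
#' @export
setClass("DffTrace",
  representation(
    time = "numeric",
    dff = "numeric",
    fs = "numeric",
    fitSlope = "numeric",
    fitIntercept = "numeric"
  )
)

setValidity("DffTrace", function(object) {
  msg <- character()
  if (length(object@dff) != length(object@time)) {
    msg <- c(msg, "time and dff must have equal length")
  }
  if (any(!is.finite(object@dff))) msg <- c(msg, "dff must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' Trials-by-time matrix of peri-event dF/F
#'
#' One row per conditioning trial on a trial-relative time axis (seconds
#' relative to CS onset). With the standard schedule each trial spans
#' [-20, 142): 20 s of pre-CS baseline through 100 s after shock offset.
#'
#' @slot values trials x timepoints matrix, percent dF/F or z-units.
#' @slot relTime uniform trial-relative time axis in seconds.
#' @slot fs Hz of the trial-relative grid.
#' @slot zscored whether rows have been z-scored by their own baseline.
#' @slot baselineWindow half-open window (seconds, CS-relative) used for
#'   z-scoring; default \code{c(-20, 0)}.
#'
#' @export
setClass("TrialMatrix",
  representation(
    values = "matrix",
    relTime = "numeric",
    fs = "numeric",
    zscored = "logical",
    baselineWindow = "numeric"
  )
)

setValidity("TrialMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@relTime)) {
    msg <- c(msg, "ncol(values) must equal length(relTime)")
  }
  if (length(object@relTime) > 1) {
    dt <- diff(object@relTime)
    if (max(abs(dt - dt[1])) > 1e-6) msg <- c(msg, "relTime must be uniform")
  }
  if (length(object@baselineWindow) != 2L ||
      object@baselineWindow[1] >= object@baselineWindow[2]) {
    msg <- c(msg, "baselineWindow must be an increasing pair")
  }
  if (isTRUE(object@zscored)) {
    bl <- object@relTime >= object@baselineWindow[1] &
      object@relTime < object@baselineWindow[2]
    if (any(bl)) {
      m <- rowMeans(object@values[, bl, drop = FALSE])
      if (max(abs(m)) > 1e-6) {
        msg <- c(msg, "zscored matrix must have per-trial baseline mean 0")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Single-channel LFP recording
#'
#' Hippocampal local field potential with sampling rate and (optionally)
#' labelled epoch windows used for incidence classification.
#'
#' @slot samples voltage samples, microvolts.
#' @slot fs sampling rate, Hz.
#' @slot epochs data.frame of epoch windows (\code{label}, \code{start},
#'   \code{end}, \code{trial_index}) or an empty data.frame.
#'
#' @export
setClass("LfpRecording",
  representation(
    samples = "numeric",
    fs = "numeric",
    epochs = "data.frame"
  )
)

setValidity("LfpRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Sharp-wave-ripple detection parameters
#'
#' Thresholds and duration rules for envelope-based SWR detection. The
#' defaults are the standard field values: 130-200 Hz band, 2 SD edge
#' threshold, 5 SD peak threshold, 20-100 ms duration bounds, 30 ms
#' minimum inter-ripple interval, 8 ms envelope smoothing.
#'
#' @slot band band-pass corner frequencies in Hz.
#' @slot edgeThreshold,peakThreshold thresholds in SD units of the normalised
#'   smoothed squared band-passed signal.
#' @slot minDuration,maxDuration event duration bounds, seconds.
#' @slot minInterRipple candidates closer than this (gap, seconds) are merged.
#' @slot envelopeSmooth moving-average smoothing window, seconds.
#'
#' @seealso [rippleParams()], [detectRipples()]
#' @export
setClass("RippleDetectionParams",
  representation(
    band = "numeric",
    edgeThreshold = "numeric",
    peakThreshold = "numeric",
    minDuration = "numeric",
    maxDuration = "numeric",
    minInterRipple = "numeric",
    envelopeSmooth = "numeric"
  )
)

setValidity("RippleDetectionParams", function(object) {
  msg <- character()
  if (length(object@band) != 2L || object@band[1] <= 0 ||
      object@band[1] >= object@band[2]) {
    msg <- c(msg, "band must be an increasing positive pair of frequencies")
  }
  if (!(object@edgeThreshold > 0 &&
        object@edgeThreshold < object@peakThreshold)) {
    msg <- c(msg, "must have 0 < edgeThreshold < peakThreshold")
  }
  if (!(object@minDuration > 0 && object@minDuration < object@maxDuration)) {
    msg <- c(msg, "must have 0 < minDuration < maxDuration")
  }
  if (object@minInterRipple < 0) msg <- c(msg, "minInterRipple must be >= 0")
  if (object@envelopeSmooth <= 0) msg <- c(msg, "envelopeSmooth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Binned freezing series
#'
#' Fraction of time spent freezing per uniform time bin, as produced by
#' video-based freezing scoring (the scoring itself is upstream of this
#' package; the series is taken as input).
#'
#' @slot binStart bin start times, seconds; uniform and non-overlapping.
#' @slot freezing freezing fraction in [0, 1] per bin.
#' @slot binWidth bin width, seconds.
#'
#' @export
setClass("FreezingSeries",
  representation(
    binStart = "numeric",
    freezing = "numeric",
    binWidth = "numeric"
  )
)

setValidity("FreezingSeries", function(object) {
  msg <- character()
  if (length(object@binStart) != length(object@freezing)) {
    msg <- c(msg, "binStart and freezing must have equal length")
  }
  if (any(object@freezing < 0 | object@freezing > 1)) {
    msg <- c(msg, "freezing fractions must lie in [0, 1]")
  }
  if (length(object@binWidth) != 1L || object@binWidth <= 0) {
    msg <- c(msg, "binWidth must be a single positive number")
  }
  if (length(object@binStart) > 1) {
    if (max(abs(diff(object@binStart) - object@binWidth)) > 1e-9) {
      msg <- c(msg, "bins must be uniform and non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})
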