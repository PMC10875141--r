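# Isosbestic dF/F pipeline: bin-mean downsampling, whole-session OLS of the
# 465 nm signal on the 405 nm control, percent dF/F, peri-CS trial
# extraction, per-trial baseline z-scoring and pre/post-shock epoch means.

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "PhotometrySession", function(object) object@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "DffTrace", function(object) object@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "LfpRecording", function(object) object@fs)

setMethod("show", "PhotometrySession", function(object) {
  cat(sprintf("PhotometrySession: %d samples at %g Hz (%.1f s)\n",
    length(object@time), object@fs, length(object@time) / object@fs))
  cat("  TTL events:", paste(names(object@ttlEvents), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "DffTrace", function(object) {
  cat(sprintf("DffTrace: %d samples at %g Hz; fit 465 ~ %.4f * 405 + %.4f\n",
    length(object@dff), object@fs, object@fitSlope, object@fitIntercept))
  invisible(NULL)
})

setMethod("show", "TrialMatrix", function(object) {
  cat(sprintf("TrialMatrix: %d trial(s) x %d timepoints, rel_time [%g, %g) s, %s\n",
    nrow(object@values), ncol(object@values), object@relTime[1],
    object@relTime[length(object@relTime)] + 1 / object@fs,
    if (object@zscored) "z-scored" else "percent dF/F"))
  invisible(NULL)
})

#' @rdname TrialMatrix-class
#' @export
setMethod("isZscored", "TrialMatrix", function(object) object@zscored)

#' Trial values accessor
#' @param tm a [TrialMatrix-class].
#' @return the trials x timepoints numeric matrix.
#' @export
trialValues <- function(tm) tm@values

#' Trial-relative time axis accessor
#' @param tm a [TrialMatrix-class].
#' @export
relTime <- function(tm) tm@relTime

#' @describeIn downsampleSession non-overlapping bin means, both channels
#'   downsampled identically; TTL events are carried through unchanged.
#' @export
setMethod("downsampleSession", "PhotometrySession", function(session, targetFs) {
  factor <- session@fs / targetFs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("invalid parameter: targetFs must divide fs (integer decimation factor)")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(session)
  n <- length(session@time)
  nOut <- n %/% factor
  idx <- seq_len(nOut * factor)
  binMean <- function(x) {
    colMeans(matrix(x[idx], nrow = factor))
  }
  newTime <- (seq_len(nOut) - 1) / targetFs
  new("PhotometrySession",
    time = newTime,
    signal465 = binMean(session@signal465),
    control405 = binMean(session@control405),
    fs = targetFs, ttlEvents = session@ttlEvents
  )
})

#' Compute isosbestic-corrected percent dF/F
#'
#' Fits an ordinary-least-squares regression predicting the 465 nm signal
#' from the 405 nm control over the whole session, then normalises the
#' actual 465 nm signal by the prediction:
#' \code{dF/F = (actual - predicted) / predicted * 100}.
#'
#' @param session a [PhotometrySession-class] (typically already downsampled
#'   to 10 Hz).
#' @return a [DffTrace-class] carrying the fit coefficients.
#' @examples
#' s <- new("PhotometrySession", time = 0:3 / 1, signal465 = c(2, 4, 6, 9),
#'          control405 = c(1, 2, 3, 4), fs = 1, ttlEvents = list())
#' computeDff(s)
#' @export
computeDff <- function(session) {
  x <- session@control405
  y <- session@signal465
  if (length(unique(x)) < 2L) {
    stop("degenerate regression: 405 nm control channel is constant")
  }
  # closed-form simple OLS
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  predicted <- intercept + slope * x
  guard <- 1e-6 * stats::median(abs(y))
  bad <- which(abs(predicted) < guard)
  if (length(bad)) {
    stop(sprintf(
      "numerical guard: |predicted 465| < eps*median(465) at samples %d-%d",
      min(bad), max(bad)))
  }
  new("DffTrace",
    time = session@time, dff = (y - predicted) / predicted * 100,
    fs = session@fs, fitSlope = slope, fitIntercept = intercept
  )
}

#' Extract peri-CS trials from a dF/F trace
#'
#' One row per trial, from 20 s before CS onset to 100 s after shock offset
#' (with the standard 20 s tone / 20 s trace / 2 s shock this is a
#' CS-relative axis of [-20, 142) — 1620 samples at 10 Hz). Rows are aligned
#' on the sample nearest each CS onset, so alignment error is at most half a
#' sample period.
#'
#' @param dff a [DffTrace-class].
#' @param schedule the [SessionSchedule-class] that produced the recording.
#' @param preOnset seconds included before CS onset.
#' @param postShock seconds included after shock offset.
#' @return a [TrialMatrix-class] with \code{zscored = FALSE}.
#' @export
extractTrials <- function(dff, schedule, preOnset = 20, postShock = 100) {
  fs <- dff@fs
  shockEndRel <- schedule@toneDuration + schedule@traceDuration +
    schedule@shockDuration
  nPre <- round(preOnset * fs)
  nPost <- round((shockEndRel + postShock) * fs)
  relIdx <- seq.int(-nPre, nPost - 1L)
  relTime <- relIdx / fs
  n <- length(dff@dff)
  rows <- lapply(seq_len(nTrials(schedule)), function(i) {
    onsetIdx <- which.min(abs(dff@time - csOnsets(schedule)[i]))
    idx <- onsetIdx + relIdx
    if (idx[1] < 1L || idx[length(idx)] > n) {
      span <- range(csOnsets(schedule)[i] + relTime)
      stop(sprintf(
        "trial %d window [%.1f, %.1f) s not covered by the recording (%.1f s)",
        i - 1L, span[1], span[2] + 1 / fs, n / fs))
    }
    dff@dff[idx]
  })
  new("TrialMatrix",
    values = do.call(rbind, rows), relTime = relTime, fs = fs,
    zscored = FALSE, baselineWindow = c(-preOnset, 0)
  )
}

#' Z-score each trial by its own pre-CS baseline
#'
#' Each row is transformed by \code{(x - mu) / sigma} where \code{mu} and
#' \code{sigma} are the mean and SD of that row over the baseline window
#' (default the 20 s before CS onset). The SD convention defaults to the
#' population SD (divide by n); set \code{sdType = "sample"} for n - 1.
#'
#' @param tm a non-z-scored [TrialMatrix-class].
#' @param sdType baseline SD convention.
#' @return the z-scored [TrialMatrix-class].
#' @export
zscoreTrials <- function(tm, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (tm@zscored) stop("trial matrix is already z-scored")
  bl <- tm@relTime >= tm@baselineWindow[1] & tm@relTime < tm@baselineWindow[2]
  if (!any(bl)) stop("baseline window contains no samples")
  vals <- tm@values
  for (i in seq_len(nrow(vals))) {
    b <- vals[i, bl]
    mu <- mean(b)
    sigma <- if (sdType == "population") {
      sqrt(mean((b - mu)^2))
    } else {
      stats::sd(b)
    }
    if (!is.finite(sigma) || sigma <= 0) {
      stop(sprintf("zero baseline SD in trial %d; cannot z-score", i - 1L))
    }
    vals[i, ] <- (vals[i, ] - mu) / sigma
  }
  new("TrialMatrix", values = vals, relTime = tm@relTime, fs = tm@fs,
      zscored = TRUE, baselineWindow = tm@baselineWindow)
}

#' Pre/post-shock epoch means
#'
#' Means over the pre-shock (trace interval, 20-40 s after CS onset with the
#' standard schedule) and post-shock (42-62 s after CS onset) windows per
#' trial, then averaged across trials to one (pre, post) pair per
#' session/animal.
#'
#' @param tm a [TrialMatrix-class].
#' @param preWindow,postWindow half-open windows in CS-relative seconds.
#' @return named numeric vector \code{c(pre = ..., post = ...)}; per-trial
#'   values are attached as attribute \code{"perTrial"}.
#' @export
epochMeans <- function(tm, preWindow = c(20, 40), postWindow = c(42, 62)) {
  windowMean <- function(win) {
    sel <- tm@relTime >= win[1] & tm@relTime < win[2]
    if (!any(sel)) {
      stop(sprintf("empty epoch window [%g, %g) after clipping", win[1], win[2]))
    }
    rowMeans(tm@values[, sel, drop = FALSE])
  }
  pre <- windowMean(preWindow)
  post <- windowMean(postWindow)
  out <- c(pre = mean(pre), post = mean(post))
  attr(out, "perTrial") <- data.frame(trial_index = seq_along(pre) - 1L,
                                      pre = pre, post = post)
  out
}

#' Read/write a photometry session as tidy CSV
#'
#' Columns \code{time_s}, \code{signal_465}, \code{control_405}; TTL events
#' in a separate two-column CSV (\code{label}, \code{time_s}).
#'
#' @param session a [PhotometrySession-class].
#' @param path CSV path for the channels.
#' @param ttlPath optional CSV path for TTL events.
#' @export
writePhotometryCsv <- function(session, path, ttlPath = NULL) {
  utils::write.csv(data.frame(
    time_s = session@time, signal_465 = session@signal465,
    control_405 = session@control405
  ), path, row.names = FALSE)
  if (!is.null(ttlPath)) {
    ev <- session@ttlEvents
    utils::write.csv(data.frame(
      label = rep(names(ev), lengths(ev)),
      time_s = unlist(ev, use.names = FALSE)
    ), ttlPath, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writePhotometryCsv
#' @param fs sampling rate of the stored series (inferred from time spacing
#'   when omitted).
#' @export
readPhotometryCsv <- function(path, ttlPath = NULL, fs = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time_s))
  ttl <- list()
  if (!is.null(ttlPath)) {
    ev <- utils::read.csv(ttlPath)
    ttl <- split(ev$time_s, ev$label)
  }
  new("PhotometrySession", time = df$time_s, signal465 = df$signal_465,
      control405 = df$control_405, fs = fs, ttlEvents = ttl)
}

#' Write a trial matrix as CSV with a rel_time header row
#' @param tm a [TrialMatrix-class].
#' @param path output CSV path.
#' @export
writeTrialMatrixCsv <- function(tm, path) {
  df <- as.data.frame(tm@values)
  names(df) <- sprintf("%g", tm@relTime)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
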