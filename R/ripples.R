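# Sharp-wave-ripple detection: zero-phase ripple-band filtering, smoothed
# squared envelope in SD units, threshold/merge/duration rules, and
# epoch-wise incidence.

#' Construct ripple detection parameters
#'
#' Defaults are the standard values: 130-200 Hz band, edges at 2 SD, peak at
#' 5 SD, 20-100 ms duration, 30 ms minimum inter-ripple interval, 8 ms
#' envelope smoothing.
#'
#' @param band,edgeThreshold,peakThreshold,minDuration,maxDuration,minInterRipple,envelopeSmooth
#'   see [RippleDetectionParams-class].
#' @return a [RippleDetectionParams-class] object.
#' @export
rippleParams <- function(band = c(130, 200), edgeThreshold = 2,
                         peakThreshold = 5, minDuration = 0.020,
                         maxDuration = 0.100, minInterRipple = 0.030,
                         envelopeSmooth = 0.008) {
  new("RippleDetectionParams", band = band, edgeThreshold = edgeThreshold,
      peakThreshold = peakThreshold, minDuration = minDuration,
      maxDuration = maxDuration, minInterRipple = minInterRipple,
      envelopeSmooth = envelopeSmooth)
}

setMethod("show", "RippleDetectionParams", function(object) {
  cat(sprintf(
    "RippleDetectionParams: band %g-%g Hz, edge %g SD, peak %g SD,\n  duration %g-%g ms, inter-ripple >= %g ms, smoothing %g ms\n",
    object@band[1], object@band[2], object@edgeThreshold,
    object@peakThreshold, 1000 * object@minDuration, 1000 * object@maxDuration,
    1000 * object@minInterRipple, 1000 * object@envelopeSmooth))
  invisible(NULL)
})

setMethod("show", "LfpRecording", function(object) {
  cat(sprintf("LfpRecording: %d samples at %g Hz (%.1f s), %d epoch window(s)\n",
    length(object@samples), object@fs, length(object@samples) / object@fs,
    nrow(object@epochs)))
  invisible(NULL)
})

# Zero-phase FIR band-pass (windowed sinc, order scaled with fs so the
# transition width in Hz is rate-independent).
bandpassFir <- function(x, fs, band) {
  order <- 2L * (round(fs / 8) %/% 2L)  # even order; 250 taps at 1 kHz
  if (length(x) < 3L * (order + 1L)) {
    stop("recording shorter than 3 filter lengths; cannot band-pass")
  }
  b <- as.numeric(signal::fir1(order, band / (fs / 2), type = "pass"))
  as.numeric(signal::filtfilt(b, 1, x))
}

lowpassFir <- function(x, fs, cutoff) {
  order <- 2L * (round(fs / 10) %/% 2L)
  if (length(x) < 3L * (order + 1L)) {
    stop("recording shorter than 3 filter lengths; cannot low-pass")
  }
  b <- as.numeric(signal::fir1(order, cutoff / (fs / 2), type = "low"))
  as.numeric(signal::filtfilt(b, 1, x))
}

#' Downsample an LFP recording with anti-alias filtering
#'
#' Zero-phase FIR low-pass (cutoff 0.4 x target rate) followed by integer
#' decimation. Returns the broadband downsampled trace; ripple-band
#' filtering happens inside detection.
#'
#' @param raw an [LfpRecording-class].
#' @param targetFs target sampling rate, Hz (default 1000).
#' @return the downsampled [LfpRecording-class].
#' @export
preprocessLfp <- function(raw, targetFs = 1000) {
  if (raw@fs < 2 * 200) {
    stop("sampling rate below the Nyquist bound for the ripple band")
  }
  factor <- raw@fs / targetFs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("invalid parameter: targetFs must divide fs")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(raw)
  filtered <- lowpassFir(raw@samples, raw@fs, 0.4 * targetFs)
  new("LfpRecording", samples = filtered[seq(1, length(filtered), by = factor)],
      fs = targetFs, epochs = raw@epochs)
}

# Smoothed squared band-passed signal (unnormalised envelope).
rippleEnvelopeRaw <- function(samples, fs, params) {
  bp <- bandpassFir(samples, fs, params@band)
  sq <- bp^2
  w <- max(1L, round(params@envelopeSmooth * fs))
  sm <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  # edge bins: extend the nearest interior value
  nas <- which(is.na(sm))
  if (length(nas)) {
    firstOk <- which(!is.na(sm))[1]
    lastOk <- max(which(!is.na(sm)))
    sm[nas[nas < firstOk]] <- sm[firstOk]
    sm[nas[nas > lastOk]] <- sm[lastOk]
  }
  sm
}

#' Normalised ripple-band power envelope
#'
#' Band-passes the recording in the ripple band (zero-phase), squares it,
#' smooths with a moving average, and z-normalises by the mean and SD of the
#' smoothed squared signal over the whole recording. Detection thresholds in
#' "standard deviations" refer to this series.
#'
#' @param lfp a preprocessed [LfpRecording-class] (typically 1 kHz).
#' @param params a [RippleDetectionParams-class].
#' @return numeric envelope in SD units, same length as the recording.
#' @export
rippleEnvelope <- function(lfp, params = rippleParams()) {
  sm <- rippleEnvelopeRaw(lfp@samples, lfp@fs, params)
  mu <- mean(sm)
  sigma <- stats::sd(sm)
  if (!is.finite(sigma) || sigma <= 1e-12 * max(mu, 1e-300)) {
    stop("degenerate envelope: ripple-band power has (near-)zero variance")
  }
  (sm - mu) / sigma
}

#' Detect sharp-wave ripples by envelope thresholding
#'
#' Candidate events are maximal runs where the normalised envelope is at or
#' above the edge threshold; runs touching the first or last sample are
#' discarded (their true extent is unknowable); candidates separated by a
#' gap shorter than the minimum inter-ripple interval are merged; merged
#' events must reach the peak threshold and have duration within the bounds.
#'
#' @param lfp a preprocessed [LfpRecording-class].
#' @param params a [RippleDetectionParams-class].
#' @param envelope optionally a precomputed envelope from [rippleEnvelope()].
#' @return data.frame with one row per event: \code{start}, \code{peak_time},
#'   \code{end} (seconds, half-open), \code{duration} (s) and
#'   \code{peak_power} (SD units), sorted by start.
#' @export
detectRipples <- function(lfp, params = rippleParams(), envelope = NULL) {
  if (is.null(envelope)) envelope <- rippleEnvelope(lfp, params)
  fs <- lfp@fs
  n <- length(envelope)
  above <- envelope >= params@edgeThreshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  s <- starts[sel]; e <- ends[sel]
  # discard runs touching the recording boundary
  keep <- s > 1L & e < n
  s <- s[keep]; e <- e[keep]
  events <- emptyRippleTable()
  if (length(s)) {
    # merge candidates whose below-threshold gap is shorter than the minimum
    # inter-ripple interval
    ms <- s[1]; me <- e[1]
    mergedS <- integer(); mergedE <- integer()
    if (length(s) > 1L) {
      for (i in 2:length(s)) {
        gap <- (s[i] - me - 1L) / fs
        if (gap < params@minInterRipple) {
          me <- e[i]
        } else {
          mergedS <- c(mergedS, ms); mergedE <- c(mergedE, me)
          ms <- s[i]; me <- e[i]
        }
      }
    }
    mergedS <- c(mergedS, ms); mergedE <- c(mergedE, me)
    rows <- lapply(seq_along(mergedS), function(i) {
      idx <- mergedS[i]:mergedE[i]
      pk <- max(envelope[idx])
      if (pk < params@peakThreshold) return(NULL)
      dur <- (mergedE[i] - mergedS[i] + 1L) / fs
      if (dur < params@minDuration || dur > params@maxDuration) return(NULL)
      pkIdx <- idx[which.max(envelope[idx])]
      data.frame(start = (mergedS[i] - 1L) / fs, peak_time = (pkIdx - 1L) / fs,
                 end = mergedE[i] / fs, duration = dur, peak_power = pk)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) events <- do.call(rbind, rows)
  }
  events <- events[order(events$start), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Literal reference detector (brute-force scan)
#'
#' A deliberately naive sample-by-sample scan that applies the edge, merge,
#' peak and duration rules literally, used to validate the vectorised
#' detector: on any input both must return identical event tables.
#'
#' @inheritParams detectRipples
#' @return same shape as [detectRipples()].
#' @export
detectRipplesBruteForce <- function(lfp, params = rippleParams(),
                                    envelope = NULL) {
  if (is.null(envelope)) envelope <- rippleEnvelope(lfp, params)
  fs <- lfp@fs
  n <- length(envelope)
  # rule 1: collect maximal suprathreshold runs by walking the samples
  runs <- list()
  inRun <- FALSE
  runStart <- NA_integer_
  for (i in seq_len(n)) {
    if (envelope[i] >= params@edgeThreshold) {
      if (!inRun) { inRun <- TRUE; runStart <- i }
    } else if (inRun) {
      runs[[length(runs) + 1L]] <- c(runStart, i - 1L)
      inRun <- FALSE
    }
  }
  if (inRun) runs[[length(runs) + 1L]] <- c(runStart, n)
  # discard boundary-touching runs
  runs <- Filter(function(r) r[1] > 1L && r[2] < n, runs)
  # rule 2: merge runs with gaps below the inter-ripple minimum
  merged <- list()
  for (r in runs) {
    if (length(merged) &&
        (r[1] - merged[[length(merged)]][2] - 1L) / fs < params@minInterRipple) {
      merged[[length(merged)]][2] <- r[2]
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  # rule 3: peak and duration tests
  out <- emptyRippleTable()
  for (r in merged) {
    idx <- r[1]:r[2]
    pk <- -Inf; pkIdx <- idx[1]
    for (j in idx) if (envelope[j] > pk) { pk <- envelope[j]; pkIdx <- j }
    dur <- (r[2] - r[1] + 1L) / fs
    if (pk >= params@peakThreshold && dur >= params@minDuration &&
        dur <= params@maxDuration) {
      out <- rbind(out, data.frame(
        start = (r[1] - 1L) / fs, peak_time = (pkIdx - 1L) / fs,
        end = r[2] / fs, duration = dur, peak_power = pk))
    }
  }
  rownames(out) <- NULL
  out
}

emptyRippleTable <- function() {
  data.frame(start = numeric(), peak_time = numeric(), end = numeric(),
             duration = numeric(), peak_power = numeric())
}

#' Epoch-wise ripple counts and incidence
#'
#' Assigns each event to the window containing its peak time (windows are
#' half-open; within a family they must not overlap) and reports counts and
#' rates in events per minute, plus the per-label mean rate (the session's
#' baseline-vs-ITI aggregate).
#'
#' @param events event table from [detectRipples()].
#' @param windows epoch-window data.frame (e.g. \code{epochWindows(sched, "swr")}).
#' @return the windows with added \code{count} and \code{rate_per_min}
#'   columns; per-label mean rates are attached as attribute
#'   \code{"aggregate"}.
#' @export
rippleIncidence <- function(events, windows) {
  counts <- integer(nrow(windows))
  if (nrow(events)) {
    for (i in seq_len(nrow(windows))) {
      counts[i] <- sum(events$peak_time >= windows$start[i] &
                       events$peak_time < windows$end[i])
    }
  }
  out <- windows
  out$count <- counts
  out$rate_per_min <- counts / ((windows$end - windows$start) / 60)
  agg <- tapply(out$rate_per_min, out$label, mean)
  attr(out, "aggregate") <- agg
  out
}

#' Write/read ripple events as a tab-separated interval file
#'
#' Columns \code{start_s}, \code{peak_s}, \code{end_s}, \code{duration_ms},
#' \code{peak_sd}.
#'
#' @param events event table from [detectRipples()].
#' @param path output path.
#' @export
writeRipplesTsv <- function(events, path) {
  utils::write.table(data.frame(
    start_s = events$start, peak_s = events$peak_time, end_s = events$end,
    duration_ms = events$duration * 1000, peak_sd = events$peak_power
  ), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRipplesTsv
#' @export
readRipplesTsv <- function(path) {
  df <- utils::read.delim(path)
  data.frame(start = df$start_s, peak_time = df$peak_s, end = df$end_s,
             duration = df$duration_ms / 1000, peak_power = df$peak_sd)
}
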