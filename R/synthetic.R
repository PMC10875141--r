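# Synthetic generators for the three input streams (photometry, LFP,
# freezing), each a pure function of (parameters, seed) with its ground
# truth returned alongside, so every analysis stage has a recoverable target.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Ground-truth parameters for the photometry generator
#'
#' Describes a synthetic GCaMP photometry session: shared exponential
#' photobleaching, a shared slow motion artifact, independent shot noise per
#' channel, and calcium transients (difference-of-exponentials kernels)
#' injected into the 465 nm channel only. Transient amplitudes are expressed
#' in percent dF/F so downstream recovery is unit-consistent.
#'
#' @param transientTimes transient onset times, seconds (default: none; the
#'   generator's standard effect places one at each shock onset, see
#'   [genPhotometry()]).
#' @param transientAmplitudes peak amplitudes in percent dF/F, recycled.
#' @param tauRise,tauDecay kernel time constants, seconds (GCaMP6f-like
#'   defaults 0.2 and 2).
#' @param bleachTau photobleaching time constant, seconds.
#' @param motionAmplitude SD of the shared slow motion artifact, a.u.
#' @param noiseSd per-sample white-noise SD, a.u., independent per channel.
#' @param baselineLevel 405 nm fluorescence level at t = 0, a.u.
#' @param gain,offset affine map from the shared component to the 465 nm
#'   channel (465 = gain * shared + offset + transients + noise).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return a classed parameter list.
#' @export
photometryTruth <- function(transientTimes = numeric(), transientAmplitudes = 5,
                            tauRise = 0.2, tauDecay = 2, bleachTau = 2500,
                            motionAmplitude = 2, noiseSd = 0.5,
                            baselineLevel = 100, gain = 1.5, offset = 10,
                            seed = 1L) {
  stopifnot(all(transientAmplitudes >= 0), tauRise > 0, tauDecay > 0,
            bleachTau > 0, motionAmplitude >= 0, noiseSd >= 0,
            baselineLevel > 0)
  structure(list(
    transientTimes = as.numeric(transientTimes),
    transientAmplitudes = rep_len(as.numeric(transientAmplitudes),
                                  max(1L, length(transientTimes))),
    tauRise = tauRise, tauDecay = tauDecay, bleachTau = bleachTau,
    motionAmplitude = motionAmplitude, noiseSd = noiseSd,
    baselineLevel = baselineLevel, gain = gain, offset = offset,
    seed = as.integer(seed)
  ), class = "PhotometryGroundTruth")
}

# Difference-of-exponentials calcium kernel, normalised to unit peak.
transientKernel <- function(t, tauRise, tauDecay) {
  tPeak <- log(tauDecay / tauRise) / (1 / tauRise - 1 / tauDecay)
  peak <- exp(-tPeak / tauDecay) - exp(-tPeak / tauRise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tauDecay) - exp(-t[pos] / tauRise)) / peak
  out
}

#' Analytic window-averaged transient response
#'
#' Mean of the unit-amplitude transient kernel over a half-open window
#' expressed relative to the transient onset, times the amplitude: the
#' ground-truth value against which pipeline epoch means are compared.
#'
#' @param truth a [photometryTruth()] object (for the kernel taus).
#' @param window numeric pair, seconds relative to transient onset.
#' @param amplitude percent dF/F amplitude (default: first truth amplitude).
#' @return the analytic mean percent dF/F contributed over the window.
#' @export
analyticEpochResponse <- function(truth, window, amplitude = truth$transientAmplitudes[1]) {
  tr <- truth$tauRise; td <- truth$tauDecay
  tPeak <- log(td / tr) / (1 / tr - 1 / td)
  peak <- exp(-tPeak / td) - exp(-tPeak / tr)
  antideriv <- function(t) -td * exp(-t / td) + tr * exp(-t / tr)
  lo <- max(window[1], 0)
  hi <- max(window[2], 0)
  if (hi <= lo) return(0)
  mass <- (antideriv(hi) - antideriv(lo)) / peak
  amplitude * mass / (window[2] - window[1])
}

#' Generate a synthetic two-channel photometry session
#'
#' Both channels share the bleaching curve and motion artifact exactly; the
#' 465 nm channel adds an affine gain/offset, calcium transients and its own
#' noise. With zero noise and no transients the channels are exactly affinely
#' related, so the isosbestic regression cancels motion and bleaching to
#' machine precision.
#'
#' @param schedule a [SessionSchedule-class]; sets the session duration and
#'   TTL event times.
#' @param truth a [photometryTruth()] parameter set.
#' @param fs sampling rate in Hz (>= 20; the acquisition endpoint emits
#'   demodulated 120 Hz streams).
#' @return list with \code{session} (a [PhotometrySession-class]) and
#'   \code{truth} (the input parameters, echoed).
#' @export
genPhotometry <- function(schedule, truth = photometryTruth(), fs = 120) {
  stopifnot(is(schedule, "SessionSchedule"))
  if (fs < 20) stop("invalid parameter: fs must be >= 20 Hz")
  duration <- sessionDuration(schedule)
  if (length(truth$transientTimes) &&
      any(truth$transientTimes < 0 | truth$transientTimes > duration)) {
    stop("invalid parameter: transient time beyond session end")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  res <- withSeed(truth$seed, {
    bleach <- truth$baselineLevel * exp(-t / truth$bleachTau)
    # slow shared motion: unit-variance knots at 1 Hz, linearly interpolated
    nKnots <- ceiling(duration) + 1L
    knots <- stats::rnorm(nKnots)
    motion <- truth$motionAmplitude *
      stats::approx(seq(0, by = 1, length.out = nKnots), knots, xout = t,
                    rule = 2)$y
    shared <- bleach + motion
    transientDff <- numeric(n)
    for (i in seq_along(truth$transientTimes)) {
      transientDff <- transientDff + truth$transientAmplitudes[i] *
        transientKernel(t - truth$transientTimes[i], truth$tauRise,
                        truth$tauDecay)
    }
    f0 <- truth$gain * shared + truth$offset
    control405 <- shared + stats::rnorm(n, 0, truth$noiseSd)
    signal465 <- f0 * (1 + transientDff / 100) +
      stats::rnorm(n, 0, truth$noiseSd)
    list(control405 = control405, signal465 = signal465)
  })

  session <- new("PhotometrySession",
    time = t, signal465 = res$signal465, control405 = res$control405, fs = fs,
    ttlEvents = list(
      session_start = 0, session_end = duration,
      cs_onset = csOnsets(schedule), shock_onset = shockOnsets(schedule)
    )
  )
  list(session = session, truth = truth)
}

#' Ground-truth parameters for the LFP ripple generator
#'
#' @param centers burst centre times, seconds.
#' @param durations full burst durations, seconds (raised-cosine support),
#'   recycled; nominal range 0.02-0.1 s.
#' @param amplitudes peak envelope amplitudes in SD multiples of the
#'   background's normalised ripple-band power, recycled.
#' @param carrierFreq carrier frequency in Hz (130-200), recycled.
#' @param seed RNG seed.
#' @return a classed parameter list.
#' @export
rippleTruth <- function(centers = numeric(), durations = 0.05, amplitudes = 8,
                        carrierFreq = 150, seed = 1L) {
  if (any(amplitudes < 0)) stop("invalid parameter: amplitude < 0")
  stopifnot(all(durations > 0), all(carrierFreq > 0))
  k <- max(1L, length(centers))
  structure(list(
    centers = as.numeric(centers),
    durations = rep_len(as.numeric(durations), k),
    amplitudes = rep_len(as.numeric(amplitudes), k),
    carrierFreq = rep_len(as.numeric(carrierFreq), k),
    seed = as.integer(seed)
  ), class = "RippleGroundTruth")
}

#' Generate a synthetic LFP recording with injected ripple bursts
#'
#' Background noise (white, or 1/f band-limited to 0.3-500 Hz to mirror a
#' typical acquisition filter) is scaled to unit SD in the 130-200 Hz band.
#' Each injected burst is a sinusoid at its carrier frequency windowed by a
#' raised-cosine envelope of the stated duration, with its carrier amplitude
#' calibrated against the background's own smoothed squared band-power so
#' that the normalised detection envelope peaks near the requested SD
#' multiple.
#'
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz (>= 1000).
#' @param truth a [rippleTruth()] parameter set.
#' @param noiseModel background model.
#' @param params detection parameters used for the power calibration
#'   (band and smoothing window).
#' @return list with \code{lfp} (an [LfpRecording-class]) and \code{truth},
#'   augmented with per-event \code{starts}/\code{ends}.
#' @export
genLfp <- function(duration, fs = 2000, truth = rippleTruth(),
                   noiseModel = c("one_over_f", "white"),
                   params = rippleParams()) {
  noiseModel <- match.arg(noiseModel)
  if (fs < 1000) stop("invalid parameter: fs must be >= 1000 Hz")
  if (any(truth$amplitudes < 0)) stop("invalid parameter: amplitude < 0")
  if (length(truth$centers)) {
    half <- truth$durations / 2
    if (any(truth$centers - half < 0 | truth$centers + half > duration)) {
      stop("invalid parameter: burst extends outside the recording")
    }
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  bg <- withSeed(truth$seed, {
    if (noiseModel == "white") {
      stats::rnorm(n)
    } else {
      # spectral synthesis: amplitude ~ 1/sqrt(f), band-limited 0.3-500 Hz
      white <- stats::rnorm(n)
      spec <- stats::fft(white)
      freqs <- c(0, seq_len(n - 1)) * fs / n
      freqs <- pmin(freqs, fs - freqs)  # two-sided
      shape <- ifelse(freqs >= 0.3 & freqs <= 500, 1 / sqrt(pmax(freqs, 0.3)), 0)
      Re(stats::fft(spec * shape, inverse = TRUE)) / n
    }
  })

  # scale background to unit SD in the ripple band
  bandSd <- stats::sd(bandpassFir(bg, fs, params@band))
  if (bandSd > 0) bg <- bg / bandSd

  # calibrate burst carrier amplitudes against the background's own smoothed
  # squared band power, as seen by the detector (at 1 kHz): for each burst
  # shape, measure the detector-envelope peak of an isolated unit-amplitude
  # burst (this absorbs the band-pass attenuation of the burst's sidebands)
  # and scale so the peak band power lands at the requested SD multiple.
  samplesOut <- bg
  if (length(truth$centers)) {
    bgRec <- new("LfpRecording", samples = bg, fs = fs,
                 epochs = emptyEpochs())
    bg1k <- if (fs > 1000) preprocessLfp(bgRec, 1000) else bgRec
    env0 <- rippleEnvelopeRaw(bg1k@samples, bg1k@fs, params)
    mu0 <- mean(env0)
    sd0 <- stats::sd(env0)
    localEnvPeak <- function(seg, centerRel, half) {
      rec <- new("LfpRecording", samples = seg, fs = fs,
                 epochs = emptyEpochs())
      rec1k <- if (fs > 1000) preprocessLfp(rec, 1000) else rec
      env <- rippleEnvelopeRaw(rec1k@samples, rec1k@fs, params)
      tEnv <- (seq_along(env) - 1) / rec1k@fs - centerRel
      max(env[abs(tEnv) <= half])
    }
    pad <- 0.8
    for (i in seq_along(truth$centers)) {
      half <- truth$durations[i] / 2
      idx <- which(t >= truth$centers[i] - half - pad &
                   t <= truth$centers[i] + half + pad)
      tt <- t[idx] - truth$centers[i]
      shape <- ifelse(abs(tt) <= half,
                      0.5 * (1 + cos(pi * tt / half)) *
                        sin(2 * pi * truth$carrierFreq[i] * tt), 0)
      # initial guess from the isolated burst's envelope response, then a few
      # fixed-point refinements on the realised local peak (absorbs the local
      # background and the cross term)
      centerRel <- truth$centers[i] - t[idx[1]]
      p1 <- localEnvPeak(shape, centerRel, half)
      amp <- sqrt(truth$amplitudes[i] * sd0 / p1)
      if (truth$amplitudes[i] > 0) {
        for (it in 1:3) {
          z <- (localEnvPeak(samplesOut[idx] + amp * shape, centerRel, half) -
                  mu0) / sd0
          ratio <- sqrt(truth$amplitudes[i] / max(z, 0.25))
          amp <- amp * min(2, max(0.5, ratio))
        }
      }
      samplesOut[idx] <- samplesOut[idx] + amp * shape
    }
  }

  truth$starts <- truth$centers - truth$durations / 2
  truth$ends <- truth$centers + truth$durations / 2
  lfp <- new("LfpRecording", samples = samplesOut, fs = fs,
             epochs = emptyEpochs())
  list(lfp = lfp, truth = truth)
}

#' Generate a freezing series linearly coupled to per-ITI ripple counts
#'
#' Per-ITI freezing fraction is
#' \code{clip(intercept + slope * count + noise, 0, 1)}, expanded to a
#' uniform per-bin series (default 0.2 s bins, a common video scoring rate).
#' Time outside the ITI windows is filled at \code{baseLevel}.
#'
#' @param schedule a [SessionSchedule-class].
#' @param rippleCounts integer vector, one SWR count per ITI (length
#'   \code{nTrials}).
#' @param slope freezing fraction per ripple count.
#' @param intercept baseline ITI freezing fraction in [0, 1].
#' @param noiseSd SD of the per-ITI Gaussian noise (fraction).
#' @param seed RNG seed.
#' @param binWidth bin width, seconds.
#' @param baseLevel freezing fraction outside ITI windows.
#' @return list with \code{series} (a [FreezingSeries-class]) and
#'   \code{itiFractions} (the ground-truth per-ITI fractions).
#' @export
genFreezing <- function(schedule, rippleCounts, slope = 0.02, intercept = 0.1,
                        noiseSd = 0.05, seed = 1L, binWidth = 0.2,
                        baseLevel = intercept) {
  stopifnot(is(schedule, "SessionSchedule"))
  if (intercept < 0 || intercept > 1) {
    stop("invalid parameter: intercept must lie in [0, 1]")
  }
  if (length(rippleCounts) != nTrials(schedule)) {
    stop("invalid parameter: rippleCounts length must equal nTrials")
  }
  frac <- withSeed(seed, {
    pmin(pmax(intercept + slope * rippleCounts +
                stats::rnorm(length(rippleCounts), 0, noiseSd), 0), 1)
  })
  duration <- sessionDuration(schedule)
  starts <- seq(0, duration - binWidth / 2, by = binWidth)
  values <- rep(baseLevel, length(starts))
  iti <- epochWindows(schedule, "behavior")
  iti <- iti[iti$label == "iti", , drop = FALSE]
  for (i in seq_len(nrow(iti))) {
    inWin <- starts >= iti$start[i] & starts < iti$end[i]
    values[inWin] <- frac[i]
  }
  series <- new("FreezingSeries", binStart = starts, freezing = values,
                binWidth = binWidth)
  list(series = series, itiFractions = frac)
}

emptyEpochs <- function() {
  data.frame(label = character(), start = numeric(), end = numeric(),
             trial_index = integer(), stringsAsFactors = FALSE)
}
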