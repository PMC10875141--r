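# End-to-end simulated experiments: simulate -> preprocess -> detect ->
# analyze, with a single global seed fanned out to per-stage substreams so
# adding a stage does not perturb earlier streams.

#' Derive a per-stage RNG substream seed
#'
#' Stable hash of the stage name combined with the global seed; the result
#' is a valid 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param stage stage name, e.g. \code{"photometry_animal_3"}.
#' @return an integer seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + h * 101) %% 2147483647)
}

#' Configuration for a simulated photometry experiment
#'
#' Defaults mirror the standard design: the 10-trial photometry schedule,
#' 11 animals, one calcium transient per footshock.
#'
#' @param nAnimals animals in the (first) group.
#' @param amplitude transient amplitude, percent dF/F (0 simulates the null).
#' @param groupBAmplitude if non-NULL, a second group of \code{nAnimals}
#'   animals with this amplitude is simulated and the groups are compared by
#'   Welch's t on (post - pre).
#' @param fs acquisition sampling rate, Hz.
#' @param zscore compute epoch means on baseline z-scored trials.
#' @param noiseSd,motionAmplitude generator noise levels (a.u.).
#' @param schedule a [SessionSchedule-class].
#' @param seed global seed.
#' @return a named configuration list.
#' @export
photometryConfig <- function(nAnimals = 11, amplitude = 5,
                             groupBAmplitude = NULL, fs = 120, zscore = TRUE,
                             noiseSd = 0.5, motionAmplitude = 2,
                             schedule = buildSchedule("photometry"),
                             seed = 1L) {
  list(kind = "photometry", nAnimals = nAnimals, amplitude = amplitude,
       groupBAmplitude = groupBAmplitude, fs = fs, zscore = zscore,
       noiseSd = noiseSd, motionAmplitude = motionAmplitude,
       schedule = schedule, seed = as.integer(seed))
}

simulateOneAnimal <- function(config, amplitude, animalSeed) {
  sched <- config$schedule
  truth <- photometryTruth(
    transientTimes = shockOnsets(sched), transientAmplitudes = amplitude,
    motionAmplitude = config$motionAmplitude, noiseSd = config$noiseSd,
    seed = animalSeed
  )
  gen <- genPhotometry(sched, truth, fs = config$fs)
  ds <- downsampleSession(gen$session, 10)
  tm <- extractTrials(computeDff(ds), sched)
  if (isTRUE(config$zscore)) tm <- zscoreTrials(tm)
  epochMeans(tm)
}

#' Run a simulated photometry experiment end to end
#'
#' Simulates a cohort, runs the full dF/F pipeline per animal, and compares
#' pre- vs post-shock epoch means with a paired t test; with a second group
#' configured, also compares (post - pre) between groups with Welch's t.
#'
#' @param config from [photometryConfig()].
#' @return report list: resolved config echo, package version, the per-animal
#'   (pre, post) table and the test results.
#' @export
runPhotometryExperiment <- function(config = photometryConfig()) {
  prePost <- do.call(rbind, lapply(seq_len(config$nAnimals), function(i) {
    em <- simulateOneAnimal(config, config$amplitude,
                            stageSeed(config$seed, paste0("photometry_A_", i)))
    data.frame(animal = sprintf("A%02d", i), group = "A",
               pre = em[["pre"]], post = em[["post"]])
  }))
  report <- list(
    config = configEcho(config), version = packageVersionString(),
    pre_post = prePost,
    paired_t = pairedT(prePost$pre, prePost$post)
  )
  if (!is.null(config$groupBAmplitude)) {
    prePostB <- do.call(rbind, lapply(seq_len(config$nAnimals), function(i) {
      em <- simulateOneAnimal(config, config$groupBAmplitude,
                              stageSeed(config$seed, paste0("photometry_B_", i)))
      data.frame(animal = sprintf("B%02d", i), group = "B",
                 pre = em[["pre"]], post = em[["post"]])
    }))
    report$pre_post <- rbind(prePost, prePostB)
    report$welch_post_minus_pre <- welchT(prePost$post - prePost$pre,
                                          prePostB$post - prePostB$pre)
  }
  report
}

#' Configuration for a simulated SWR experiment
#'
#' Defaults place ripples at a baseline incidence of 1.5 events/min and an
#' ITI incidence of 3 events/min (a 2x post-shock increase), with burst
#' amplitudes of 8-12 SD and a positive freezing-count coupling.
#'
#' @param nAnimals number of animals.
#' @param baselineRate,itiRate ground-truth incidence, events/min.
#' @param amplitudeRange injected burst amplitudes, SD multiples (uniform).
#' @param durationRange injected burst durations, seconds (uniform).
#' @param lfpFs acquisition sampling rate, Hz.
#' @param freezingSlope,freezingIntercept,freezingNoiseSd coupling of per-ITI
#'   freezing to ripple counts (fraction per count; fraction; fraction).
#' @param schedule a [SessionSchedule-class].
#' @param seed global seed.
#' @return a named configuration list.
#' @export
swrConfig <- function(nAnimals = 3, baselineRate = 1.5, itiRate = 3,
                      amplitudeRange = c(8, 12), durationRange = c(0.05, 0.1),
                      lfpFs = 2000, freezingSlope = 0.02,
                      freezingIntercept = 0.1, freezingNoiseSd = 0.05,
                      schedule = buildSchedule("photometry"), seed = 1L) {
  list(kind = "swr", nAnimals = nAnimals, baselineRate = baselineRate,
       itiRate = itiRate, amplitudeRange = amplitudeRange,
       durationRange = durationRange, lfpFs = lfpFs,
       freezingSlope = freezingSlope, freezingIntercept = freezingIntercept,
       freezingNoiseSd = freezingNoiseSd, schedule = schedule,
       seed = as.integer(seed))
}

# place n event centres uniformly in [start, end) with a minimum separation
placeEvents <- function(n, start, end, minSep = 0.5, margin = 0.1) {
  if (n == 0) return(numeric())
  centers <- numeric(0)
  tries <- 0
  while (length(centers) < n && tries < 10000) {
    cand <- stats::runif(1, start + margin, end - margin)
    if (!length(centers) || min(abs(centers - cand)) >= minSep) {
      centers <- c(centers, cand)
    }
    tries <- tries + 1
  }
  sort(centers)
}

simulateSwrAnimal <- function(config, animalSeed) {
  sched <- config$schedule
  win <- epochWindows(sched, "swr")
  centers <- withSeed(animalSeed, {
    unlist(lapply(seq_len(nrow(win)), function(i) {
      rate <- if (win$label[i] == "swr_baseline") config$baselineRate else config$itiRate
      n <- stats::rpois(1, rate * (win$end[i] - win$start[i]) / 60)
      placeEvents(n, win$start[i], win$end[i])
    }))
  })
  k <- max(1L, length(centers))
  pars <- withSeed(animalSeed + 1L, list(
    durations = stats::runif(k, config$durationRange[1], config$durationRange[2]),
    amplitudes = stats::runif(k, config$amplitudeRange[1], config$amplitudeRange[2])
  ))
  truth <- rippleTruth(centers = centers, durations = pars$durations,
                       amplitudes = pars$amplitudes, carrierFreq = 150,
                       seed = animalSeed + 2L)
  gen <- genLfp(sessionDuration(sched), fs = config$lfpFs, truth = truth)
  lfp1k <- preprocessLfp(gen$lfp, 1000)
  events <- detectRipples(lfp1k)
  inc <- rippleIncidence(events, win)
  agg <- attr(inc, "aggregate")
  itiWin <- win[win$label == "swr_iti", , drop = FALSE]
  trueCounts <- vapply(seq_len(nrow(itiWin)), function(i) {
    sum(centers >= itiWin$start[i] & centers < itiWin$end[i])
  }, integer(1))
  fz <- genFreezing(sched, trueCounts, slope = config$freezingSlope,
                    intercept = config$freezingIntercept,
                    noiseSd = config$freezingNoiseSd, seed = animalSeed + 3L)
  list(events = events, incidence = inc, aggregate = agg,
       freezing = fz$series, truth = truth)
}

#' Run a simulated SWR experiment end to end
#'
#' Full chain per animal: LFP generation with injected ripples ->
#' preprocessing -> detection -> epoch incidence, plus a freezing series
#' coupled to the injected per-ITI counts. Reports baseline-vs-ITI incidence
#' (paired t across animals) and the pooled freezing-SWR Pearson test.
#'
#' @param config from [swrConfig()].
#' @return report list with per-animal incidence, the tests and config echo.
#' @export
runSwrExperiment <- function(config = swrConfig()) {
  sims <- lapply(seq_len(config$nAnimals), function(i) {
    simulateSwrAnimal(config, stageSeed(config$seed, paste0("swr_animal_", i)))
  })
  names(sims) <- sprintf("A%02d", seq_len(config$nAnimals))
  rates <- do.call(rbind, lapply(names(sims), function(a) {
    agg <- sims[[a]]$aggregate
    data.frame(animal = a, baseline_rate = unname(agg["swr_baseline"]),
               iti_rate = unname(agg["swr_iti"]))
  }))
  pairs <- swrFreezingPairs(lapply(sims, `[[`, "events"),
                            lapply(sims, `[[`, "freezing"), config$schedule)
  report <- list(
    config = configEcho(config), version = packageVersionString(),
    incidence = rates,
    paired_t_incidence = pairedT(rates$baseline_rate, rates$iti_rate),
    swr_freezing_pairs = pairs,
    pearson_freezing_swr = pearsonTest(pairs$swr_count,
                                       pairs$iti_freezing_percent)
  )
  report
}

configEcho <- function(config) {
  sched <- config$schedule
  config$schedule <- list(
    baseline_duration = sched@baselineDuration, n_trials = sched@nTrials,
    tone_duration = sched@toneDuration, trace_duration = sched@traceDuration,
    shock_duration = sched@shockDuration, iti_duration = sched@itiDuration
  )
  config
}

packageVersionString <- function() {
  as.character(utils::packageVersion("tracephys"))
}

#' Serialise a report to JSON
#'
#' Deterministic serialisation (full-precision numbers, stable field order):
#' identical config + seed give byte-identical output.
#'
#' @param report a report list from a \code{run*Experiment} function.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
reportJson <- function(report, path = NULL) {
  js <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
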