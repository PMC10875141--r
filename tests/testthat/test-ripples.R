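# Ripple detection: preprocessing, envelope, threshold/merge/duration rules
# (against hand-built envelopes with known answers), the brute-force
# reference, and incidence.

test_that("rippleParams carries the standard defaults", {
  p <- rippleParams()
  expect_equal(p@band, c(130, 200))
  expect_equal(p@edgeThreshold, 2)
  expect_equal(p@peakThreshold, 5)
  expect_equal(c(p@minDuration, p@maxDuration), c(0.020, 0.100))
  expect_equal(p@minInterRipple, 0.030)
  expect_equal(p@envelopeSmooth, 0.008)
})

test_that("preprocessLfp decimates with anti-alias filtering", {
  fs <- 2000
  t <- (0:(10 * fs - 1)) / fs
  tone <- sin(2 * pi * 150 * t)
  rec <- new("LfpRecording", samples = tone, fs = fs,
             epochs = tracephys:::emptyEpochs())
  ds <- preprocessLfp(rec, 1000)
  expect_equal(samplingRate(ds), 1000)
  expect_equal(length(ds@samples), length(tone) / 2)
  # a ripple-band tone passes through the anti-alias filter unattenuated
  expect_equal(stats::sd(ds@samples), stats::sd(tone), tolerance = 0.01)
  expect_error(preprocessLfp(rec, 1500), "must divide fs")
  slow <- new("LfpRecording", samples = tone[1:1000], fs = 300,
              epochs = tracephys:::emptyEpochs())
  expect_error(preprocessLfp(slow), "Nyquist")
})

test_that("rippleEnvelope rejects degenerate input", {
  flat <- new("LfpRecording", samples = rep(0, 2000), fs = 1000,
              epochs = tracephys:::emptyEpochs())
  expect_error(rippleEnvelope(flat), "degenerate envelope")
  short <- new("LfpRecording", samples = stats::rnorm(100), fs = 1000,
               epochs = tracephys:::emptyEpochs())
  expect_error(detectRipples(short), "shorter than 3 filter lengths")
})

# build an envelope of `n` samples with suprathreshold runs described by
# (start sample, end sample, peak value) triples
buildEnvelope <- function(n, runs) {
  env <- rep(0, n)
  for (r in runs) {
    idx <- r[[1]]:r[[2]]
    env[idx] <- 2          # exactly at the edge threshold
    env[idx[ceiling(length(idx) / 2)]] <- r[[3]]
  }
  env
}

test_that("a clean suprathreshold run becomes one event with exact fields", {
  env <- buildEnvelope(2000, list(list(501L, 540L, 6)))
  ev <- detectRipples(envelopeCarrier(2000), envelope = env)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 0.500)
  expect_equal(ev$end, 0.540)
  expect_equal(ev$duration, 0.040)
  expect_equal(ev$peak_power, 6)
  expect_equal(ev$peak_time, 0.519)  # sample 520, zero-based time
})

test_that("sub-peak, sub-duration and over-duration runs are rejected", {
  carrier <- envelopeCarrier(2000)
  subPeak <- buildEnvelope(2000, list(list(501L, 540L, 4.9)))
  expect_equal(nrow(detectRipples(carrier, envelope = subPeak)), 0)
  tooShort <- buildEnvelope(2000, list(list(501L, 515L, 6)))
  expect_equal(nrow(detectRipples(carrier, envelope = tooShort)), 0)
  tooLong <- buildEnvelope(2000, list(list(501L, 650L, 6)))
  expect_equal(nrow(detectRipples(carrier, envelope = tooLong)), 0)
})

test_that("exact threshold and duration boundaries are inclusive", {
  carrier <- envelopeCarrier(2000)
  # edges exactly 2, peak exactly 5, duration exactly 20 ms
  atMin <- buildEnvelope(2000, list(list(501L, 520L, 5)))
  ev <- detectRipples(carrier, envelope = atMin)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 0.020)
  # duration exactly 100 ms
  atMax <- buildEnvelope(2000, list(list(501L, 600L, 6)))
  expect_equal(detectRipples(carrier, envelope = atMax)$duration, 0.100)
})

test_that("runs separated by less than 30 ms merge; exactly 30 ms do not", {
  carrier <- envelopeCarrier(2000)
  # gap = (551 - 530 - 1)/1000 = 20 ms -> merged into one 80 ms event
  merged <- buildEnvelope(2000, list(list(501L, 530L, 6), list(551L, 580L, 4)))
  ev <- detectRipples(carrier, envelope = merged)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 0.500)
  expect_equal(ev$end, 0.580)
  expect_equal(ev$duration, 0.080)
  # gap exactly 30 ms -> two separate events (both must pass the peak rule)
  apart <- buildEnvelope(2000, list(list(501L, 530L, 6), list(561L, 590L, 6)))
  expect_equal(nrow(detectRipples(carrier, envelope = apart)), 2)
  # merging can push duration past the maximum, discarding the pair
  longPair <- buildEnvelope(2000,
                            list(list(501L, 560L, 6), list(581L, 640L, 6)))
  expect_equal(nrow(detectRipples(carrier, envelope = longPair)), 0)
})

test_that("runs touching the recording boundary are discarded", {
  carrier <- envelopeCarrier(2000)
  atStart <- buildEnvelope(2000, list(list(1L, 40L, 6)))
  expect_equal(nrow(detectRipples(carrier, envelope = atStart)), 0)
  atEnd <- buildEnvelope(2000, list(list(1961L, 2000L, 6)))
  expect_equal(nrow(detectRipples(carrier, envelope = atEnd)), 0)
})

test_that("detector and brute-force reference agree on generated LFP", {
  for (seed in 1:5) {
    truth <- rippleTruth(centers = c(3, 6.5, 9), durations = 0.06,
                         amplitudes = c(9, 11, 8), seed = seed)
    gen <- genLfp(12, fs = 1000, truth = truth)
    env <- rippleEnvelope(gen$lfp)
    fast <- detectRipples(gen$lfp, envelope = env)
    slow <- detectRipplesBruteForce(gen$lfp, envelope = env)
    expect_identical(fast, slow)
    expect_gte(nrow(fast), 1)
  }
})

test_that("rippleIncidence counts peak times per half-open window", {
  events <- data.frame(
    start = c(9.99, 30.01, 60.5, 95.0), peak_time = c(10.0, 30.02, 60.55, 95.01),
    end = c(10.05, 30.06, 60.6, 95.06), duration = 0.05, peak_power = 6)
  win <- data.frame(label = c("swr_baseline", "swr_iti", "swr_iti"),
                    start = c(0, 30, 90), end = c(30, 60, 120),
                    trial_index = c(NA, 0L, 1L))
  inc <- rippleIncidence(events, win)
  expect_equal(inc$count, c(1L, 1L, 1L))   # 60.55 falls in no window
  expect_equal(inc$rate_per_min, c(2, 2, 2))
  agg <- attr(inc, "aggregate")
  expect_equal(unname(agg["swr_baseline"]), 2)
  expect_equal(unname(agg["swr_iti"]), 2)
})

test_that("ripple events round-trip through TSV", {
  events <- data.frame(start = c(1.0, 2.5), peak_time = c(1.02, 2.53),
                       end = c(1.06, 2.58), duration = c(0.06, 0.08),
                       peak_power = c(6.5, 7.2))
  path <- tempfile(fileext = ".tsv")
  writeRipplesTsv(events, path)
  back <- readRipplesTsv(path)
  expect_equal(back, events)
  unlink(path)
})
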