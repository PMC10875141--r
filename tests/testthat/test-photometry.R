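# dF/F pipeline: regression, downsampling, trial extraction, z-scoring,
# epoch means, and I/O.

makeSession <- function(signal465, control405, fs = 1) {
  n <- length(signal465)
  new("PhotometrySession", time = (seq_len(n) - 1) / fs,
      signal465 = signal465, control405 = control405, fs = fs,
      ttlEvents = list())
}

test_that("computeDff reproduces the closed-form OLS fit", {
  # hand-worked example: x = 1:4, y = (2, 4, 6, 9)
  # slope = cov/var = 2.3, intercept = mean(y) - slope * mean(x) = -0.5
  s <- makeSession(c(2, 4, 6, 9), c(1, 2, 3, 4))
  dff <- computeDff(s)
  expect_equal(dff@fitSlope, 2.3, tolerance = 1e-12)
  expect_equal(dff@fitIntercept, -0.5, tolerance = 1e-12)
  predicted <- -0.5 + 2.3 * c(1, 2, 3, 4)
  expect_equal(dff@dff, (c(2, 4, 6, 9) - predicted) / predicted * 100,
               tolerance = 1e-12)
  # cross-check the fit against lm()
  fit <- stats::lm(y ~ x, data = data.frame(x = c(1, 2, 3, 4),
                                            y = c(2, 4, 6, 9)))
  expect_equal(unname(stats::coef(fit)), c(-0.5, 2.3), tolerance = 1e-10)
})

test_that("computeDff rejects a constant control channel", {
  s <- makeSession(c(2, 4, 6, 9), rep(3, 4))
  expect_error(computeDff(s), "control channel is constant")
})

test_that("computeDff guards against near-zero predicted fluorescence", {
  # predicted = 2x - 4 hits zero at the middle sample
  s <- makeSession(c(-2, 0, 2), c(1, 2, 3))
  expect_error(computeDff(s), "numerical guard")
})

test_that("downsampleSession takes exact non-overlapping bin means", {
  s <- makeSession(as.numeric(1:12), as.numeric(12:1), fs = 6)
  ds <- downsampleSession(s, 2)
  expect_equal(samplingRate(ds), 2)
  expect_equal(ds@signal465, c(2, 5, 8, 11))
  expect_equal(ds@control405, c(11, 8, 5, 2))
  expect_equal(ds@time, c(0, 0.5, 1, 1.5))
  expect_error(downsampleSession(s, 4), "integer decimation")
})

test_that("extractTrials returns 10 x 1620 at 10 Hz for the standard design", {
  sched <- buildSchedule("photometry")
  gen <- genPhotometry(sched, photometryTruth(noiseSd = 0.1, seed = 2),
                       fs = 20)
  tm <- extractTrials(computeDff(downsampleSession(gen$session, 10)), sched)
  expect_equal(dim(trialValues(tm)), c(10, 1620))
  expect_equal(relTime(tm)[1], -20)
  expect_equal(relTime(tm)[1620], 141.9)
  expect_false(isZscored(tm))
})

test_that("extractTrials refuses trials that overrun the recording", {
  sched <- smallSchedule()
  gen <- genPhotometry(sched, photometryTruth(noiseSd = 0.1, seed = 2),
                       fs = 20)
  dff <- computeDff(downsampleSession(gen$session, 10))
  expect_error(extractTrials(dff, sched, postShock = 130),
               "not covered by the recording")
})

test_that("zscoreTrials matches the hand-worked baseline statistics", {
  b <- c(3, 5, 7, 4, 6, 5, 4, 6, 5, 5)   # mean 5, population SD sqrt(1.2)
  row <- c(b, 9, 0, 0, 0, 0)
  tm <- new("TrialMatrix", values = matrix(row, nrow = 1),
            relTime = (-10:4) / 10, fs = 10, zscored = FALSE,
            baselineWindow = c(-1, 0))
  zpop <- zscoreTrials(tm)
  expect_equal(trialValues(zpop)[1, 11], 4 / sqrt(1.2), tolerance = 1e-12)
  zsmp <- zscoreTrials(tm, sdType = "sample")
  expect_equal(trialValues(zsmp)[1, 11], 4 / stats::sd(b), tolerance = 1e-12)
  expect_true(isZscored(zpop))
  expect_error(zscoreTrials(zpop), "already z-scored")
})

test_that("zscoreTrials rejects a zero-variance baseline", {
  tm <- new("TrialMatrix", values = matrix(c(rep(1, 10), 5, 6), nrow = 1),
            relTime = (-10:1) / 10, fs = 10, zscored = FALSE,
            baselineWindow = c(-1, 0))
  expect_error(zscoreTrials(tm), "zero baseline SD in trial 0")
})

test_that("epochMeans averages the half-open windows per trial", {
  vals <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  tm <- new("TrialMatrix", values = vals, relTime = c(0, 1, 2, 3), fs = 1,
            zscored = FALSE, baselineWindow = c(-1, 0))
  em <- epochMeans(tm, preWindow = c(0, 2), postWindow = c(2, 4))
  expect_equal(unname(em), c(mean(c(1.5, 5.5)), mean(c(3.5, 7.5))),
               ignore_attr = TRUE)
  per <- attr(em, "perTrial")
  expect_equal(per$pre, c(1.5, 5.5))
  expect_equal(per$post, c(3.5, 7.5))
  expect_error(epochMeans(tm, preWindow = c(10, 12)), "empty epoch window")
})

test_that("photometry sessions round-trip through CSV", {
  sched <- smallSchedule()
  gen <- genPhotometry(sched, photometryTruth(seed = 9), fs = 20)
  path <- tempfile(fileext = ".csv")
  ttl <- tempfile(fileext = ".csv")
  writePhotometryCsv(gen$session, path, ttl)
  back <- readPhotometryCsv(path, ttl)
  expect_equal(back@signal465, gen$session@signal465)
  expect_equal(samplingRate(back), 20)
  expect_equal(sort(back@ttlEvents$cs_onset), csOnsets(sched))
  unlink(c(path, ttl))
})

test_that("trial matrices export with a rel_time header", {
  tm <- new("TrialMatrix", values = matrix(1:6, nrow = 2, byrow = TRUE) * 1.0,
            relTime = c(-0.1, 0, 0.1), fs = 10, zscored = FALSE,
            baselineWindow = c(-0.1, 0))
  path <- tempfile(fileext = ".csv")
  writeTrialMatrixCsv(tm, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(back), c("-0.1", "0", "0.1"))
  expect_equal(unname(as.matrix(back)), trialValues(tm))
  unlink(path)
})
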