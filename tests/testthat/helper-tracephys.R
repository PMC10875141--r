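# Shared fixtures for the test suite.

# A short 3-trial schedule with the standard trial structure, used where a
# full 10-trial session would only add runtime.
smallSchedule <- function(n = 3L) {
  buildSchedule("custom", nTrials = n)
}

# An LfpRecording shell used to exercise the detector against hand-built
# envelopes (the detector only needs the sampling rate in that mode).
envelopeCarrier <- function(n, fs = 1000) {
  new("LfpRecording", samples = numeric(n), fs = fs,
      epochs = tracephys:::emptyEpochs())
}

# Greedy matching of detected events to injected ground truth with a
# tolerance on the interval edges; returns c(matched, detected, truth).
matchEvents <- function(events, truth, tol = 0.010) {
  usedTruth <- rep(FALSE, length(truth$centers))
  matched <- 0L
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      hit <- which(!usedTruth &
                     events$peak_time[i] >= truth$starts - tol &
                     events$peak_time[i] <= truth$ends + tol)
      if (length(hit)) {
        usedTruth[hit[1]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  c(matched = matched, detected = nrow(events),
    truth = length(truth$centers))
}
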