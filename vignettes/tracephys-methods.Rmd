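---
title: "tracephys: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tracephys: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tracephys models a trace-fear-conditioning (TFC) experiment with three
measurement streams — bulk-fluorescence fiber photometry, hippocampal LFP
with sharp-wave-ripple (SWR) detection, and freezing behavior — plus the
statistics used to relate them. Every analysis stage has a matching
synthetic generator that returns its ground truth, so the whole pipeline is
testable end to end without animal recordings. This vignette documents the
model, the parameter choices, and the numerical decisions.

## Session model

A TFC session is a baseline period followed by `nTrials` repetitions of
tone (CS), silent trace interval, footshock (US), and intertrial interval
(ITI). Two built-in profiles cover the standard designs:

```{r}
library(tracephys)
buildSchedule("photometry")   # 120 s baseline, 10 trials, 20/20/2 s, 120 s ITI
buildSchedule("optogenetic")  # 240 s baseline, 3 trials, 240 s ITI
```

All intervals are half-open `[start, end)`, so adjacent epochs tile the
session without double-counting boundary samples. `epochWindows()` derives
three window families from one schedule:

* `behavior`: baseline, tone, trace, shock and ITI windows (these tile the
  session exactly);
* `photometry`: `pre_shock` (the trace interval, 20–40 s after CS onset
  with the standard trial) and `post_shock` (the equal-length window
  starting at shock offset, 42–62 s after CS onset; the 2 s shock belongs
  to neither);
* `swr`: the 120 s immediately before the first tone (`swr_baseline`) and
  the first 120 s after each shock (`swr_iti`).

## Photometry pipeline

The ΔF/F pipeline follows the isosbestic-regression convention:

1. Bin-mean both channels down to 10 Hz (`downsampleSession`). Downsampling
   precedes regression so the fit sees the same bandwidth that is analysed.
2. Fit one ordinary-least-squares regression predicting the 465 nm signal
   from the 405 nm control over the *whole session* (`computeDff`), then
   `dF/F = (actual − predicted) / predicted × 100`.
3. Extract peri-CS trials from 20 s before tone onset to 100 s after shock
   offset (`extractTrials`; 1620 samples per trial at 10 Hz).
4. Z-score each trial on its own 20 s pre-tone baseline (`zscoreTrials`).
   The baseline SD uses the population convention (divide by n) by default;
   `sdType = "sample"` selects n − 1.
5. Average the pre-shock and post-shock windows per trial and across trials
   (`epochMeans`), giving one (pre, post) pair per animal.

The generator (`genPhotometry`) writes both channels as a *shared*
component — exponential photobleaching (τ = 2500 s) plus a slow motion
artifact (unit-variance knots at 1 Hz, linearly interpolated) — with an
affine gain/offset into the 465 nm channel, independent Gaussian noise per
channel, and difference-of-exponentials calcium transients
(τ~rise~ = 0.2 s, τ~decay~ = 2 s, unit peak; GCaMP6f-like) injected into
the 465 nm channel only, scaled in percent ΔF/F. Because the artifact is
exactly affine between channels, the regression cancels it to machine
precision in the zero-noise limit — this is a designed identity, verified
in the acceptance suite. `analyticEpochResponse()` integrates the kernel in
closed form so epoch-mean recovery can be checked against exact ground
truth (a 5% transient at shock onset contributes 0.264% ΔF/F to the
post-shock window mean).

What the generator does not model: hemodynamic contamination, wavelength-
dependent (non-affine) motion coupling, indicator nonlinearity and
saturation, or spectral crosstalk. The motion-cancellation identity is
therefore an upper bound on what isosbestic regression achieves on real
recordings.

## SWR detection

`preprocessLfp` downsamples the acquisition-rate LFP (2 kHz default) to
1 kHz with a zero-phase FIR anti-alias low-pass (cutoff 0.4 × target rate).
`rippleEnvelope` then band-passes 130–200 Hz (zero-phase windowed-sinc FIR,
order `fs/8`, ≈250 taps at 1 kHz — a ≈16 Hz transition band), squares,
smooths with an 8 ms moving average, and z-normalises by the mean and SD of
the smoothed squared signal over the whole recording. `detectRipples`
applies the literal rules: candidate events are runs ≥ 2 SD; runs touching
the recording boundary are discarded; candidates separated by < 30 ms are
merged; merged events must reach 5 SD at the peak and last 20–100 ms.
`detectRipplesBruteForce` is a deliberately naive sample-by-sample
implementation of the same rules kept as a permanent cross-check: the two
must agree exactly on any input.

`genLfp` synthesises 1/f background band-limited to 0.3–500 Hz (or white
noise), scaled to unit SD in the ripple band, and adds raised-cosine-
windowed sinusoidal bursts. Burst "amplitude" is specified in SD multiples
of the *detector's own normalised envelope*; because the band-pass
attenuates a short burst's sidebands and the local background adds a cross
term, the carrier amplitude is calibrated per burst by a short fixed-point
iteration against the realised local envelope (within ~3% of the request).

### A known limitation, on purpose

On *stationary Gaussian* background the normalised smoothed squared band
power has an exponential-like tail (the 8 ms smoother leaves roughly two
effective degrees of freedom), so the 2 SD/5 SD rules admit roughly
0.25–0.3 false events per second regardless of the injected events. At 50
true ripples per 300 s this caps precision near 0.4, and merging with
nearby noise runs pushes some true 50–100 ms events past the 100 ms maximum
(merged events are discarded, not split), capping recall near 0.8. Real
recordings escape this because genuine high-power events and
non-stationarity inflate the normalisation SD. The detector is kept
literal, the generator's amplitudes realistic (8–12 SD), and the measured
precision/recall are reported honestly by `scripts/acceptance.R`; the
corresponding acceptance test states the ideal bounds and fails.

## Behavior and coupling

`genFreezing` draws one freezing fraction per ITI as
`clip(intercept + slope × SWR count + noise, 0, 1)` (defaults 0.1 + 0.02
per event, noise SD 0.05) and expands it to 0.2 s bins, a common video
scoring rate. `epochFreezing` averages bins over windows with fractional
overlap weighting, so epoch means are invariant to bin refinement.
`swrFreezingPairs` pools (animal, ITI) pairs of freezing percent and SWR
count; the pooled table feeds the Pearson test with df = pairs − 2.

## Statistics

`pairedT`, `welchT`, `pearsonTest`, `mixedAnova` (split-plot two-way ANOVA
with one between- and one within-subject factor) and `sidakAdjust`/
`sidakPosthoc` are implemented from their defining closed forms, with R's
`pt`/`pf` as the distribution layer, and carry explicit degenerate-input
contracts (zero-variance differences, exactly collinear correlations,
missing phases) instead of silent NaNs. The test suite cross-checks each
against the independent base-R route (`t.test`, `cor.test`,
`aov(... + Error(animal/phase))`) and verifies the k = 2 identity
F~interaction~ = t² on per-animal phase differences.

## Determinism and seeds

All generators are pure functions of (parameters, seed); `stageSeed()`
hashes a stage name with the global seed so per-animal and per-stage
substreams are independent and insertion-stable — adding a stage never
perturbs earlier streams. `reportJson()` serialises reports with
full-precision numbers and stable field order, so identical config + seed
give byte-identical reports.

## Problem sizes

The Monte-Carlo sizes used in the tests and the acceptance script are this
package's own choices, set to keep a single-CPU run within minutes:
null-calibration replicates use a 3-trial schedule sampled at 20 Hz, power
replicates use the full 10-trial design at a reduced 20 Hz acquisition rate
(downsampling to 10 Hz analysis bins is unchanged), and detection
benchmarks use 300 s of 1 kHz background. Every routine accepts the
full-scale parameters (120 Hz photometry, 2 kHz LFP) and the end-to-end
`runPhotometryExperiment()`/`runSwrExperiment()` defaults mirror the
standard designs (11 animals; 3 animals with baseline 1.5 and ITI 3
events/min).

## Worked example

```{r}
set.seed(1)
cfg <- photometryConfig(nAnimals = 11, amplitude = 5, fs = 120, seed = 1L)
rep <- runPhotometryExperiment(cfg)
rep$paired_t

swr <- runSwrExperiment(swrConfig(nAnimals = 3, seed = 1L))
swr$paired_t_incidence
swr$pearson_freezing_swr
```
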