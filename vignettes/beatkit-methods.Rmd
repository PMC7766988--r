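---
title: "Detecting and annotating cardiac beat fiducials with beatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and annotating cardiac beat fiducials with beatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatkit)
```

## The problem

Supervised algorithms for cardiac time series — R-peak detectors,
signal-quality classifiers, heart-rate-variability pipelines — are only as
good as the labelled reference data they are trained and validated on.
Building such references means placing three kinds of annotations on raw
recordings: instantaneous *fiducials* (an R-peak, a pulse foot), *partitions*
with a start and an end (an artefact, an intervention), and fixed-length
*epochs* carrying categorical labels (ten-second signal-quality scores).
beatkit implements that annotation data model headlessly, two automatic
fiducial detectors to pre-fill it, an evaluation harness to score detections
against references, and synthetic generators whose ground truth is exact, so
the whole chain is testable without clinical data.

## The ECG R-peak detector

The detector processes the ECG sequentially in blocks (default 0.5 s) with a
state variable carrying everything across block boundaries, so beats split
between blocks are found exactly once and the result does not depend on
where the boundaries fall.

**Enhancement.** Each block is convolved with a single-scale Mexican-hat
(Ricker) wavelet and rectified: \(Y = |x * \psi_\sigma|\). The width
parameter \(\sigma\) (default 0.015 s) puts the kernel's peak frequency
response, \(1/(\sqrt2\,\pi\sigma) \approx 15\) Hz, inside the 10–25 Hz band
where QRS energy concentrates, while P and T waves (≲ 5 Hz) and baseline
wander are suppressed. The kernel is forced to exact zero mean after
discretisation — a DC segment must map to \(Y = 0\), not to cancellation
dust — and unit L2 norm; record ends are mirror-padded. True multiscale
maxima-line tracking buys little for beat detection and is not attempted:
"modulus maxima" here means rectification followed by local-maximum search.

**Adaptive threshold.** Two running levels summarise the recent past of
\(Y\):

* a *noise level*: an exponential moving average (coefficient 0.2 per
  block) of the per-block standard deviation of \(Y\);
* a *signal level*: a quasi-peak detector — a first-order IIR envelope
  follower with a fast attack (time constant 10 ms) when the input exceeds
  the current level and a slow decay (1.5 s) otherwise, so it rides down
  from the last beat's amplitude towards the next.

The block threshold is \(T = c\,(w_n N + w_s Q)\) with default weights
\(w_n = w_s = 1\) and scale \(c = 0.35\). The scale trades early, small
beats (premature beats, fast rhythms) against tall T-waves; 0.35 was fixed
once on the synthetic suite so that detection stays perfect at 20 dB SNR and
degrades monotonically below, and is exposed like every other constant.
Because every quantity in the chain is homogeneous of degree one in the
input, detections are invariant to amplitude scaling.

Candidates are local maxima of \(Y\) strictly above \(T\); two candidates
closer than the refractory period (default 0.25 s, the 240 bpm physiological
ceiling) compete and the larger survives. A candidate near the end of the
processed data is held in the state until the refractory window has elapsed.
Since a fresh state starts with both levels at zero, the whole-record
wrapper first primes the levels on the opening two seconds (emitting
nothing) and then streams from sample one — otherwise any pre-beat wiggle in
the first block would sit above a near-zero threshold, and the result would
depend on the first block's length.

**Refinement.** Each candidate is mapped to the raw-ECG apex (largest
|deviation| from the record median within ±40 ms, a sign-robust choice that
also handles inverted leads) and refined by fitting a parabola through the
apex sample and its two neighbours:
\(\delta = \tfrac12 (y_- - y_+)/(y_- - 2y_0 + y_+)\), clamped to
±0.5 samples, with \(\delta = 0\) for a flat triple. On an exactly
parabolic peak this recovers the vertex to machine precision; on
band-limited peaks it reduces the mean timing error roughly tenfold
relative to the sample grid.

## The PPG fiducial detector

The PPG detector is derivative-based. The signal is low-pass filtered
(Butterworth order 4, cutoff 10 Hz) and differentiated (central
differences, units/s). Filtering is applied forward–backward
(zero-phase): an annotation tool must not report fiducials delayed by the
filter's group delay, which is the one deliberate departure from a
real-time implementation. The rectified derivative
(`zero_clamp`) feeds the same adaptive-threshold machinery as the ECG
detector — only the default scale differs (\(c = 0.55\)), chosen so that
the smaller derivative peak of the *diastolic* rise does not fire the
upstroke detector between beats.

Per detected upstroke:

* **foot** — last upward zero-crossing of the derivative before the
  upstroke; **systolic peak** — first downward crossing after it. Crossing
  times are linearly interpolated between the bracketing samples (the
  sub-sample analogue of the ECG parabola fit); amplitudes are read off the
  filtered signal. A beat missing either crossing (record edges, monotone
  tails) is rejected rather than extrapolated — only complete
  foot/upstroke/peak triples are emitted, so those three series always have
  equal lengths.
* **shoulder** — first trough of the derivative strictly between upstroke
  and peak, absent in unimodal rises.
* **dicrotic notch / secondary peak** — the next upward-then-downward
  derivative crossing pair after the peak. (After the systolic peak the
  derivative is negative, so the notch — a local minimum of the pulse — is
  necessarily the *upward* crossing and the rebound peak the *downward*
  one.) The pair is accepted only if the notch falls within
  `dn_time_window` (default 2.0) times the beat's rise time after the peak
  and within `dn_amp_window` (default 1.0) times the foot-to-peak amplitude
  below the peak; the secondary peak has its own windows. These
  proportional windows are calibration constants of this implementation,
  not published values.

Two structural guards keep numerics out of the morphology: a crossing pair
whose positive lobe never closes before the next upstroke is the next
beat's systole, not a diastolic rebound, and is discarded; and any
derivative excursion smaller than 2 % of the beat's upstroke amplitude is
treated as filter ripple, not as a shoulder or notch. Unfound fiducials are
reported absent (`NA` per beat, missing from their series) — never guessed.

Timestamps are invariant to amplitude scaling and DC offset, and to the
block segmentation of the upstroke detector, by the same arguments as for
the ECG.

## Evaluation

Detections and references are paired one-to-one at tolerance \(\tau\):
a sweep over both sorted sequences matches events with
\(|t_d - t_r| \le \tau\), ties going to the earlier detection. For this
interval-compatibility structure the greedy sweep attains the maximum
possible pairing cardinality; the suite verifies it against an exhaustive
augmenting-path matcher on a thousand random instances. From the counts:
\(F_1 = 2\,\mathrm{TP}/(2\,\mathrm{TP} + \mathrm{FP} + \mathrm{FN})\) and
the error rate \((\mathrm{FP} + \mathrm{FN})/\mathrm{TP}\) — "false
detections" is read as both error kinds; an FP-only mode is a flag. The
default tolerances are 50 ms (about half a normal QRS width) and 125 ms
(half the beat period at 240 bpm). \(F_1\) is non-decreasing in \(\tau\).

## The synthetic generators

`gen_ecg()` renders each beat as a sum of Gaussian waves (P, Q, R, S, T)
placed relative to the beat origin. Q and S are symmetric about R, so the
analytic apex of the superposition coincides with the R-Gaussian centre and
the stored truth is exact by construction, with heart rate (fixed, jittered,
or a breakpoint profile), QRS width, and wave amplitudes as the controllable
morphology axes. This is deliberately *not* a coupled-oscillator dynamical
model: for exercising a detector, exact truth and controllable morphology
matter more than physiological trajectory realism.

`gen_ppg()` renders each pulse as a primary Gaussian (steep rise to a
rounded peak, rise time 25 % of the beat period by default) plus an
optional delayed, narrower secondary Gaussian (35 % of the period after the
peak, relative amplitude 0.35) whose superposition creates the dicrotic
notch and secondary peak. Truth for all five fiducials is extracted from
the *continuous* model on a 2 kHz grid with parabolic refinement, so it
does not inherit the output sampling grid. Two edge conventions make
detector and truth agree exactly on which beats exist: a lead-in pulse
before \(t = 0\) (so the record opens on a decay and the first in-record
beat has a genuine onset trough), and no pulse is rendered whose diastolic
tail would cross the record end.

`add_noise()` superimposes, deterministically per seed: white Gaussian
noise at a requested SNR (measured against the clean signal's variance and
realised within 0.5 dB on 30-s records), sinusoidal baseline wander, and
square-windowed noise bursts of 0.5–2 s — a crude but sufficient stand-in
for motion artefacts when exercising threshold adaptation.

What the generators do **not** emulate: realistic HRV spectra, ectopy and
arrhythmic morphology changes, skin-contact and perfusion effects on PPG
shape, or broadband artefact structure. Perfect scores on clean synthetic
signals therefore demonstrate the internal consistency of the pipeline —
detector, truth bookkeeping, matching — not clinical-grade performance;
published benchmark databases remain the standard for the latter, and the
WFDB readers plus the CSV interfaces exist so such data can be fed through
the same harness unchanged.

## Annotation semantics

* Fiducial insertion respects a per-series minimum distance; a conflicting
  insertion is *rejected* (series unchanged, flagged) rather than
  replacing the neighbour — non-destructive by default, with `replace =
  TRUE` as the explicit alternative.
* Timestamps are real-valued seconds throughout, so sub-sample refinement
  survives the round trip into the annotation model.
* Partitions within one set must not overlap; touching endpoints are legal.
* Epochs are half-open windows \([kL, (k+1)L)\); the trailing partial
  window is labelable; the boundary instant belongs to the later epoch.
* Quality labels use five flat codes (0–4) that bijectively encode a
  quality score (Q0/Q1/Q2) and, above Q0, a morphology score (M0/M1) —
  votes enter adjudication as flat codes because that is what annotators
  assign. Adjudication defaults to: unanimity among three → consensus; any
  disagreement → fourth reviewer; 3-to-1 among four → that label; else
  group escalation. A looser reading (2-of-3 majority suffices) is behind
  `majority_ok = TRUE`.

## Persistence

`save_workspace()` writes a self-describing HDF5 layout (`/meta`,
`/tracks/<name>`, `/annotations/<name>`, `/partitions`, `/epochs`) with all
floating-point data as 64-bit doubles, so `load_workspace()` reproduces
every timestamp exactly; the suite checks `save ∘ load = identity` over
randomized workspaces and that generic HDF5 tools can walk the documented
layout. The schema carries a version stamp and the loader refuses files
from a newer major version. The layout is this package's own contract — no
compatibility with any other tool's HDF5 files is claimed.

## Numerical choices, in one place

* Low-pass filtering pads with an odd reflection (continuous value and
  slope) of at least one second before `filtfilt`, because the underlying
  filter starts from zero state.
* Wavelet and derivative edge handling: mirror padding.
* Enhanced-signal values below \(10^{-12}\) of the block amplitude are
  clamped to zero (cancellation dust must not become structure for a
  purely relative threshold).
* Local-maximum ties on plateaus resolve to the last plateau sample;
  candidate ties within a refractory window resolve to the larger, then
  the earlier.
* Refinement is clamped to ±0.5 samples and falls back to the grid at
  array edges.
* The upstroke-vs-peak precision comparison in the suite uses baseline
  drift plus mild white noise: drift tilts the waveform and moves the
  rounded extrema while barely touching the steep systolic edge, which is
  the regime where the upstroke's robustness advantage shows. Under pure
  in-band white noise after the 10 Hz low-pass the two are comparable.

## Problem sizes

The test suite and the acceptance script run on 30–120 s synthetic records
at 250 Hz (ECG) and 125 Hz (PPG): six clean ECG conditions (three rates ×
two QRS widths), three clean PPG rates, ten noisy records per SNR level at
{30, 20, 10, 5} dB, 1000 random matcher instances, and 100 random
workspaces. These sizes were chosen as the smallest that exercise every
code path with stable statistics.

## Limitations

* The detectors assume a dominant QRS deflection and a single systolic
  rise per beat; P/Q/S/T-wave delineation and beat classification are out
  of scope.
* No internal resampling: ECG below 100 Hz and PPG below 25 Hz are
  rejected rather than resampled.
* The PPG search windows and all threshold constants are calibrated on the
  synthetic suite, not reproduced from any published parameter set.
* WFDB support covers headers, signal formats 212/16 and standard
  annotation words — enough to read the common beat-annotated databases,
  not the full format family.
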