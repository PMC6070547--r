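---
title: "Radar heart-sound monitoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radar heart-sound monitoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarheart)
```

## The measurement model

A continuous-wave radar interferometer pointed at the chest measures the
radial displacement of the body surface. The Six-Port receiver outputs four
baseband voltages `b3..b6` whose differential pairs form a complex sample

    Z = I + iQ = (b5 - b6) + i (b3 - b4).

For an ideal receiver, a target at relative range `dx` traces the unit
circle with phase `dsigma = 2*pi * dx / (lambda/2)`, where `lambda = c/f` is
the carrier wavelength (12.4 mm at 24.17 GHz). The displacement follows from
the unwrapped argument of `Z`:

    dx = dsigma / (2*pi) * lambda / 2.

Chest-surface motion superimposes three cardiorespiratory components at very
different scales: breathing (millimetres, 0.1-0.5 Hz), the pulse wave (tens
of micrometres, 0.75-3 Hz), and the S1/S2 heart sounds — short vibration
bursts of roughly 10 um with spectral content between 16 and 80 Hz. The
package's claim, following the measurement principle it implements, is that
the heart-sound bursts are recoverable from the radar displacement and can
drive beat-by-beat monitoring.

### Baseband-error compensation

Receiver impairments (offsets, gain and phase imbalance) deform the ideal
unit-circle I/Q locus into an offset, tilted ellipse, which corrupts the
arctangent demodulation. `fit_ellipse()` estimates the locus by a direct
algebraic least-squares conic fit with the ellipse constraint
(Fitzgibbon-type, in the numerically stable partitioned form, on
centred/scaled coordinates). The algebraic fit is deterministic and needs no
initialisation; five coarsely distributed points suffice in principle, and
the fit can be re-applied on windows during a long recording
(`demodulate(refit_window = ...)`) if the error state drifts.

`compensate_iq()` applies, in order: offset subtraction, rotation by the
negative tilt, per-axis scaling by the inverse semi-axes. The final
back-rotation by the tilt is deliberately omitted: it is a constant phase
offset, and every downstream quantity uses phase *differences*, so it
cancels. Wrapped phase uses the `[-pi, +pi)` branch; unwrapping corrects
consecutive jumps whose magnitude exceeds exactly `pi` by multiples of
`2*pi`. Zero-magnitude samples have no defined phase and raise an error by
default; `zero_policy = "hold"` repeats the previous phase instead, the
tolerant choice for noisy hardware data.

A practical conditioning fact drives one simulator default: the ellipse is
only identifiable from the arc the target actually traces. A breathing
amplitude of 1.5 mm (the simulator default, ordinary chest-wall motion)
sweeps well over half the locus and the fit is robust at realistic noise; at
0.3 mm the arc shrinks to ~40 degrees and the conic fit becomes
ill-conditioned under any noise. Scenes with shallow breathing remain
configurable, but they are genuinely hard for any ellipse-based
compensation — a physical limitation, not an implementation one.

## The filter bank

All band separation uses fourth-order Butterworth bandpasses:
respiration 0.1-0.5 Hz, pulse wave 0.75-3.0 Hz, ECG conditioning
0.5-20 Hz, and two heart-sound bands — 25-400 Hz (variant A, the classic
phonocardiogram setting) and 16-80 Hz (variant B, the radar-adjusted band:
physiological heart sounds live below 80 Hz, and the radar's areal
integration over the chest adds low-frequency content).

Filtering is zero-phase (forward-backward) by default, because segment
*onset times* feed the interbeat-interval statistics and must not be
shifted by group delay; a causal single pass is selectable. "Fourth order"
refers to the designed prototype before the forward-backward pass (the
effective magnitude response is eighth order). Edges are handled by
odd-reflection padding of at least two periods of the band's lower edge.

Two numerical choices matter here:

* A 0.1-0.5 Hz quartic bandpass at fs = 2000 Hz is unstable in
  transfer-function form (poles crowd z = 1). `extract_component()`
  therefore decimates in anti-aliased stages to an intermediate rate at
  which the band is well conditioned (lower edge at least 0.4% of the
  working rate, upper edge at most 40%), filters there, and interpolates
  back with a spline. For band-limited signals the spline error is far
  below the filter's own ripple.
* The mean is removed before filtering: a bandpass excludes DC anyway, and
  removing it first avoids the long step-response transient.

## Heart-sound segmentation

Segmentation uses a duration-dependent hidden Markov model (hidden
semi-Markov model) over four states in fixed cyclic order:
S1 -> systole (without S1) -> S2 -> diastole (without S2) -> S1. The longer
the system has resided in a state, the more likely it leaves it; this is
encoded by explicit per-state duration distributions rather than geometric
dwell times.

**Durations.** S1 and S2 durations are normal with 122 +/- 22 ms and
92 +/- 22 ms (empirical values for healthy adults). The remaining two
states depend on the heart rate, which the model does not know a priori;
their means are derived per recording from the estimated cycle `c` as
`max(0.3*c - 0.122, 0.05)` s for systole and `max(0.7*c - 0.092, 0.05)` s
for diastole, with sd 25% of the mean. The fractions 0.3/0.7 make the four
state means sum to the estimated cycle and match the physiological rule of
thumb that systole occupies about a third of the cycle. Duration supports
are truncated at +/- 3 sd (discretised at the frame rate and renormalised),
which bounds the extended Viterbi's inner loop.

**Cycle estimate.** The heart cycle is the lag of the maximum of the
autocorrelation of the smoothed heart-sound envelope, searched only within
the variant's limits: 0.5-2.0 s for variant A (30-120 bpm) and
0.45-1.45 s for variant B (41-133 bpm).

**Emissions.** Four envelope features are computed per 10 ms frame:
homomorphic envelope (low-passed log magnitude envelope, exponentiated),
Hilbert (analytic-signal magnitude) envelope, and RMS band power in the
lower and upper halves of the variant band (geometric-mean split). Each
feature is standardised per recording, which makes decoding invariant to
uniform amplitude scaling; a constant feature standardises to zeros. A
one-vs-rest logistic regression per state turns the features into
per-frame state probabilities.

Before decoding, the posteriors are divided by the training class priors
and renormalised. One-vs-rest posteriors implicitly carry the state
frequencies, and the duration model *also* encodes how long each state
lasts; leaving both in place double-counts the prior and systematically
shrinks the rare, short S1/S2 states at their boundaries. With the
correction, the decoded S1/S2 segment-duration means reproduce the
generating 122/92 ms distributions without bias — the acceptance script
recomputes exactly this.

**Decoding.** The extended Viterbi maximises the sum of per-frame log
emission scores plus per-segment log duration probabilities, subject to the
cyclic order; first and last (truncated) segments are scored with the same
duration pmf. Ties are broken toward the earlier state change, making the
decoder deterministic. The implementation is validated against an
independent brute-force oracle that enumerates every legal segmentation of
small random instances and scores them with the same objective (the test
suite runs 200 such instances).

**Resolution choices.** The frame rate default is 100 Hz and the
homomorphic low-pass cut-off 20 Hz. Coarser settings (50 Hz frames, 8 Hz
envelope smoothing, as in common phonocardiogram segmenters) work, but
smear segment boundaries outward by several milliseconds — enough to bias
the decoded duration means beyond their sampling error. Both are
configurable (`variant_config()`, `hs_features()`).

**Silence gate.** A scale-invariant burst gate (excess kurtosis of the
smoothed envelope above 2.5) marks input without transient structure —
silence, flat noise — as unsegmentable, returning an empty segmentation
instead of hallucinating a cycle. A model that always emits a cycle is
correct on real monitoring data but needs a defined behaviour on degenerate
synthetic input.

**Training labels.** When no hand labels exist, reference labels are
derived from ECG ground truth: S1 starts after the R-peak, S2 after the
T-wave end, with durations from the duration model. The synthetic
generator provides these fiducials exactly.

## Morphology, respiration and timing analyses

* `compare_morphology()`: the PCG measures acceleration while the radar
  measures displacement, so the PCG segment is integrated twice
  (differentiating the radar would amplify its noise), aligned by the lag
  of the maximum cross-correlation, trimmed to the overlap, and compared by
  the Pearson coefficient (normalised zero-lag cross-correlation).
  Integration drift is controlled by an endpoint-anchored linear detrend
  after each pass: unlike a least-squares line, the endpoint line vanishes
  for periodic content spanning whole cycles, so it does not tilt the very
  waveform being compared. Positive lag means the second input trails the
  first.
* `segment_snr()`: per-beat ratio (dB) of the heart-sound segment RMS to
  the following quiet segment's RMS — S1 against the subsequent systole,
  S2 against the subsequent diastole. RMS is the default amplitude
  statistic; peak-to-peak is selectable.
* `peak_envelope_series()` / `respiratory_correlation()`: the per-beat
  difference between upper and lower peak envelopes (PPE) carries
  respiratory amplitude modulation of the heart sounds. Both the PPE series
  (resampled to a uniform grid) and the respiration-sensor signal are
  filtered to 0.1-0.5 Hz before correlating; the sign is preserved because
  the coupling occurs both in phase and inverted in real recordings, with
  no predictable pattern — the simulator exposes the sign as a parameter.
* `s2_split_gap()`: the aortic/pulmonary (A2/P2) split of S2 during
  inspiration is measured as the time between the two most prominent local
  maxima of the 10 ms-smoothed segment envelope, provided the secondary
  peak reaches 30% of the main peak and a trough separates them; otherwise
  "no split". The 10 ms smoothing resolves the 35 ms physiological minimum
  gap.
* `propagation_velocity()`: path difference over arrival-time difference
  between two regions of interest, for checking that S1 and S2 propagate at
  tissue pulse-wave speeds (a few m/s).

## Beat metrics

Beat events are ECG R-peaks (reference) and decoded S1 segment starts
(detected). `ibi_series()` emits one interbeat-interval value per second:
the median of the five most recent intervals, undefined until five
intervals exist; `ibi_rmse()` compares two such series over their common
defined timestamps. `match_events()` performs greedy one-to-one nearest
matching within +/- 100 ms by default — the tolerance is reported with
every F-score because the underlying convention varies between studies.
F1 is the harmonic mean of precision and recall, guarded to 0 at empty
denominators. `cross_validate()` enumerates all train/test subject splits
(`choose(11, 6) = 462` for the 11-subject/6-training design) and can cap
how many are actually evaluated; the cap is a deterministic, evenly spaced
subsample.

## The synthetic scene generator

`scene_config()` + `generate_recording()` produce fully labelled
multichannel recordings: four Six-Port baseband voltages, PCG, ECG and
respiration at fs = 2000 Hz. The generator emulates exactly the structure
the pipeline assumes:

* respiration sinusoid (default 0.25 Hz, 1.5 mm) plus one pulse-wave bump
  per beat (50 um, 80 ms Gaussian) plus S1/S2 bursts
  (Gaussian-windowed cosines at 30/45 Hz; 10/8 um; durations drawn from
  the 122 +/- 22 / 92 +/- 22 ms model, truncated at 3 sd; the +/- 3 sigma
  Gaussian window spans the drawn duration, giving closed-form second
  derivatives for the PCG);
* a beat schedule with slow sinusoidal heart-rate drift and white cycle
  jitter; S1 onset 40 ms after the R-peak, S2 onset 10 ms after the T-wave
  end, systole scaled to 0.3 of the cycle (consistent with the decoder's
  derived duration means and with systole occupying about a third of the
  cycle);
* respiratory amplitude modulation of the bursts with configurable depth
  and sign, and an optional A2-P2 split of S2 during inspiratory
  half-cycles;
* I/Q distortion as a direct affine map of the unit circle onto an offset,
  tilted ellipse — the exactly invertible equivalent of offset plus
  gain/phase imbalance — with per-channel white noise, and a symmetric
  common-mode split into the four voltages (only the channel differences
  are contractual);
* an ECG sum-of-Gaussians template whose only contractual features are the
  R-peak and T-end placement, with 0.1-0.5 Hz baseline wander;
* an optional tapping pattern in the lead-in window, with the PCG delayed
  by a configurable inter-sensor offset, exercising the tapping-based
  synchronisation.

"Subjects" for cross-validation are independent seeds with per-subject
parameter jitter (rate, amplitudes), which is what makes train/test splits
meaningful. All randomness is fixed by one seed; identical seeds give
bit-identical recordings.

**What the generator does not emulate** — and hence what green tests do not
show about hardware data: no electromagnetic propagation, antenna pattern
or multipath; no areal integration over the radar spot (the main source of
radar/PCG morphology differences in practice); no sensor drift or motion
artefacts; no arrhythmias or pathological sounds; burst waveshape is an
idealised Morlet-like pulse rather than a measured valve signature. Results
on synthetic scenes bound the algorithmic error, not the physical one.

## Problem sizes and runtime posture

The test suite trains emission models on two or three 30-40 s synthetic
subjects and decodes held-out scenes of 25-60 s; the duration-calibration
check pools about 440 beats from six 60 s recordings, a size at which the
standard error of the duration means is below 1 ms. The brute-force
decoding oracle runs on instances of 7-13 frames, where full enumeration
is exact and cheap. These sizes were chosen so the whole suite settles in
about a minute while keeping every statistical margin interpretable.

## Known limitations

* The ellipse fit needs the target to sweep an appreciable arc; shallow
  breathing (< ~0.5 mm at 24 GHz) degrades compensation fundamentally.
* The systole/diastole duration parameterisation (0.3/0.7 cycle fractions,
  25% relative sd, 50 ms floor) is a modelling choice; published segmenters
  do not restate theirs for radar data.
* Emissions are a four-feature logistic regression; the feature extractor
  is pluggable, and richer feature sets would likely be needed for
  pathological recordings.
* The recording container is a plain-text CSV with a JSON header — simple
  and lossless, but not suited to hour-scale archives.
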