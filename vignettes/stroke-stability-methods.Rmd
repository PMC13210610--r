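---
title: "Quantifying rowing-stroke stability from gyroscope recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rowing-stroke stability from gyroscope recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokestab)
```

## The measurement problem

A rower's upper back tilts rhythmically with every stroke: backwards while
the athlete works against the ergometer load (the *drive*), forwards while
the body returns to the catch (the *recovery*). A body-fixed MEMS gyroscope
— in practice, a smartphone strapped to the upper back — records the angular
velocity of this tilt about the transverse axis, `omega_x(t)`, at about
1 kHz. In the sign convention used throughout this package the drive has
negative angular velocity and the recovery positive.

Two aspects of technique can be read off such a record: the *timing
structure* of the stroke (the full period `T` and the durations `T1`, `T2`
of its drive and recovery phases) and the *stability* of the movement
pattern, i.e. how tightly individual strokes cluster around the athlete's
mean stroke curve. Both are useful longitudinally: a training block can
leave the overall cadence untouched while systematically redistributing
time between the two phases.

## Processing model

### Spectral smoothing

Raw gyroscope traces carry broadband sensor and soft-tissue noise. The
package removes it with a brick-wall Fourier filter
(`lowpass_fourier()`): the record's discrete Fourier transform is taken
as-is (no padding, windowing or detrending), every coefficient at a
frequency strictly above the cut-off is set to zero, and the signal is
reconstructed by the inverse transform. The default cut-off is
`f_cutoff = 2.23` Hz, corresponding to a period of 0.45 s; since
realistic stroke periods are 2–4 s, the filter keeps at least the
fundamental and four higher harmonics of the stroke (see
`retained_harmonics()`), and the stroke's curve shape is essentially
carried by the first three harmonics. The bin sitting exactly on the
cut-off is retained ("exceeding" the cut-off is read strictly). A
brick-wall cut was chosen over tapered FIR/IIR designs because the
downstream shape analysis relies on exact harmonic retention: components
below the cut-off must pass bit-for-bit unchanged.

Edge handling was an open choice; transforming the full record without
padding is the simplest consistent one, and with records minutes long the
leakage at the cut-off boundary is negligible for the sub-2.23 Hz band.

### Stroke segmentation

Strokes are delimited by transitions of the smoothed signal from negative
to positive values between successive samples (`find_upcrossings()`), the
moment the body reverses from drive into recovery. Crossing times are
refined by linear interpolation between the bracketing samples: durations
are reported to 0.01 s, and interpolation removes the ±1 ms quantization
of snapping to sample indices. A sample exactly equal to zero terminates
the preceding sign run, so a zero lying between a negative and a positive
sample produces one crossing at its own time.

`segment_strokes()` keeps only complete strokes (data before the first
and after the last crossing are discarded). Within a stroke, phase 2
(recovery) is the total time the signal is positive, accumulated over
*all* positive sub-intervals between interpolated sign changes, and
phase 1 is the remainder — so `T = T1 + T2` holds exactly by
construction even if smoothing leaves small ripples with extra interior
zeros. Because boundaries are up-crossings, the recovery sub-interval
precedes the drive chronologically inside each segmented stroke; phase
labels follow the sign convention, not chronological order, and the
duration statistics are unaffected. Strokes shorter than 0.45 s (the
cut-off period) are flagged but never silently removed, since no
principled rejection rule is part of the analysis.

### Duration statistics and the mean stroke profile

`summarize_durations()` reports per-trial means and sample standard
deviations (n − 1 denominator throughout; for a single stroke the SD is
reported as missing, not zero). Group-level tables
(`group_summary()`) aggregate the *participants' per-trial means* — not
pooled strokes — because the longitudinal tests operate on participant-level
values; a consequence worth knowing is that group phase means need not sum
exactly to the group full-stroke mean when trials lose different windows.

`mean_profile()` realizes "aligned stroke subsets" as fixed-length
windows of duration `<T>` (the mean period) anchored at each stroke
onset, with `round(<T>/dt) + 1` grid points and linear interpolation at
the fractional onset. Alternatives — truncation to the shortest stroke, or
time-normalized resampling — were rejected because the stability integral
below runs over `[0, <T>]` on an absolute time axis. Windows that would
overrun the record are dropped. With stroke-to-stroke period jitter the
window tail reaches into the following stroke, which inflates the
point-wise SD near the very end of the grid; this is a property of the
fixed-window alignment and the reason dispersion comparisons should focus
on the window interior.

### The instability index

The whole-stroke instability criterion computed by `stability_index()` is

$$\frac{STD(\omega_x)}{|\omega_x|} \;=\; \frac{1}{\langle T\rangle}
\int_0^{\langle T\rangle}
\frac{STD(\omega_x)(t)}{\left|\langle\omega_x\rangle(t)\right|}\,dt
\;\times\;100\%,$$

a period-normalized average of the point-wise coefficient of variation of
the stroke ensemble. The integrand is undefined at zeros of the mean
curve: both window endpoints (stroke boundaries are zero crossings) and,
for a clean two-phase stroke, exactly one interior zero — the canonical
three excluded points. The implementation generalizes this to endpoints
plus the *pair of samples bracketing every* interior sign change (and any
grid point where the mean is exactly zero), so ripple-induced extra zeros
do not break the computation; whether the original convention removed one
sample or the bracketing pair per zero is not documented anywhere, and the
bracketing pair is the choice made here. Each removed point splits the
domain and the trapezoidal rule is applied piecewise to what remains.
Two further choices: normalization is by the full `<T>` (the printed form
of the criterion), not by the slightly smaller retained measure; and the
absolute value of the mean curve is used in the denominator so the index
is non-negative. No epsilon floor regularizes small mean values — large
integrand values near phase boundaries are informative, and indices above
100% are representable and never clipped.

On an analytic two-window ensemble `(1 ± eps) * s(t)` the index has the
closed form `100 * eps * sqrt(2)` times the retained-measure fraction,
which the test suite checks at `eps = 0.1` (≈ 14.1%).

### Exact longitudinal tests

With seven athletes per stage, asymptotic test approximations are
unreliable — a continuity correction can flip a borderline 0/1 call. The
package therefore computes *exact* two-sided p-values:

* `ranksum_exact()` — the rank-sum statistic's full permutation null,
  via a subset-sum counting recursion equivalent to enumerating all
  `choose(n1 + n2, n1)` assignments; mid-ranks under ties, with the
  permutation distribution computed on the tied ranks.
* `signed_rank_exact()` — the positive-rank-sum null over all `2^m` sign
  assignments, computed by convolution; zero differences are dropped
  before ranking (the classical convention; Pratt's alternative changes
  p-values at n = 7, which is why the choice is documented).

Two-sided p-values use the doubling convention
`min(1, 2 min(P(W ≤ w), P(W ≥ w)))`. `build_test_matrix()` applies both
tests to every (stage pair × grade × quantity) cell, separately for mean
durations and for their per-trial SDs, and reports raw p-values plus 0/1
calls at `alpha = 0.05`. No multiple-testing correction is applied — the
matrices mirror the raw-per-comparison reporting convention of small
pilot cohorts — and the output carries an explicit `mt_correction = "none"`
marker. The headline `significance_counts()` universe is the sequential
stage pairs × grades × two phases (12 cells with three grades);
first-to-last comparisons are computed but counted separately.

## The synthetic-data generator

`generate_record()` and `generate_cohort()` produce records with known
ground truth so that every stage of the pipeline is testable without any
field data. The generator emulates:

* an asymmetric periodic waveform built from the fundamental plus second
  and third harmonics — the components that carry the stroke's shape. The
  default amplitudes and phases are fixed package constants, tuned once
  by root-finding so the negative (drive) lobe occupies exactly
  `2.1/3.3` of the period, matching the typical 2.1 s / 1.2 s split of a
  3.3 s stroke; they are configuration, not fitted values;
* stroke-to-stroke period jitter (`period_jitter_sd`, default 0.08 s —
  about a 2.5% coefficient of variation, typical of steady ergometer
  rowing), implemented by time-rescaling whole cycles so the waveform
  stays continuous at stroke boundaries (the template is zero there);
* amplitude jitter (default 5%) as a per-stroke scale factor;
* additive Gaussian noise synthesized in the frequency domain and
  confined to 3–40 Hz (default SD 0.15 rad/s), entirely above the
  2.23 Hz cut-off, so the smoothing stage's effect is analytically
  predictable — the noise is removed exactly;
* a trial length of 72 strokes (default), about one 4-minute test stage.

`generate_cohort()` adds participant-level structure: a random baseline
period per athlete (between-participant SD 0.15 s by default, the order
of magnitude of group tables of stroke periods), a period shortening of
0.1 s per power grade, and per-stage phase-duration shifts realized by
piecewise-linear time warping of the template's two lobes — which makes
the "phase redistribution at constant full period" scenario exactly
constructible with exact ground truth.

What the generator does **not** emulate: waveform shape changes beyond
the phase warp (real athletes change harmonic content across power
grades), non-Gaussian and non-stationary noise, sensor drift or
re-mounting offsets between sessions, and fatigue trends within a trial.
Passing tests on synthetic cohorts therefore validate the *pipeline
mechanics* — segmentation accuracy, statistical calibration, signature
detection — not the biomechanical fidelity of any particular dataset.

## Numerical choices and degenerate inputs

* Crossing localization, phase measure and window extraction all use
  linear interpolation; durations are exact to well under a millisecond
  on noiseless input.
* Discrete Fourier transforms are computed exactly at any record length:
  mixed-radix FFTs degrade to near-quadratic cost when the length has a
  large prime factor, so such lengths are transformed with Bluestein's
  chirp-z algorithm on 2-3-5-smooth FFT sizes — the result is the exact
  DFT, not a padded approximation, keeping the no-padding design intact.
* Records with fewer than two up-crossings fail segmentation with an
  explicit error; profiles need at least two usable windows; the
  stability index refuses an identically zero mean curve and warns (but
  proceeds) when the interior zero count differs from one.
* An all-zero paired difference vector makes the signed-rank test
  degenerate; it returns p = 1 with a warning rather than failing.
* In the reader, timestamps deviating from uniformity by more than 10%
  of the median step trigger linear-interpolation resampling; real
  sensor streams drop samples, and rejecting such files outright would
  discard usable recordings.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic data
at the study's own scale where that is cheap (7 participants × 3 stages ×
3 grades × 72 strokes at 1 kHz for the headline pipeline run), and on
reduced grids elsewhere chosen as the package's own validation sizes: the
phase-additivity sweep uses 10,000 strokes at a 2 ms step, jitter-recovery
runs use 200-stroke records, the null-calibration check uses 10,000
replicate tests at n = 7, and the longitudinal-signature check uses
cohorts of 7 participants × 2 stages × 20 strokes at a 5 ms step across
50 seeds. A 5 ms step keeps the Nyquist frequency at 100 Hz, far above
both the signal band and the noise band, so the reduced grids exercise
the identical code paths.

## Known limitations

* Only the x-axis gyroscope channel is analysed; no multi-axis fusion.
* No stroke-exclusion logic (e.g. the settling strokes at the start of a
  bout); all complete strokes enter the statistics, with short strokes
  flagged.
* The fixed-window alignment inflates end-of-window dispersion under
  period jitter (see above); curve registration methods are out of scope.
* The rank-sum test is applied across stages of the same cohort, where
  samples are not independent; the package computes the standard exact
  test and leaves the interpretation to the analyst, as is conventional
  for these matrices.
* p-values are reported without multiplicity adjustment, by design.
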