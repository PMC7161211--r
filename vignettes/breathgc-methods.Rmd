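---
title: "Methods: breath GC–MS signal processing and exposure-group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath GC–MS signal processing and exposure-group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathgc)
```

## The problem

Exhaled breath sampled onto a sorbent and run through GC–MS yields, per
sample, a total-ion chromatogram: detector intensity as a function of
retention time. In an exposure study the same subjects are sampled before
exposure (condition A), immediately after (B), and two hours after (C); the
question is whether and where along the retention axis the breath
composition changes. The chemistry of interest (for indoor swimming pools:
chloramines, trihalomethanes and other chlorination by-products, plus
endogenous volatiles) elutes in broad ranges — readily volatile compounds
early, semi-volatile around the middle of the run, hardly volatile late —
so the analysis layer works on three retention windows rather than on
identified compounds. Compound identification, classifier training and
instrument control are out of scope.

## Peak model and feature set

Detection operates directly on the 1-D signal with no peak-shape
assumption. An interior sample is a local maximum when it strictly exceeds
both neighbours; an equal-valued plateau strictly above both neighbours
counts once, at its middle index (the lower middle for even plateaus — a
convention fixed purely for determinism). For a maximum at index $i$:

* **Prominence.** Extend from the apex in each direction until a sample
  strictly higher than $y_i$ or the signal end; the side minimum is the
  lowest sample of that stretch, and
  $P_i = y_i - \max(m_{\text{left}}, m_{\text{right}})$. When a stretch
  minimum is attained at several indices, the base is the one closest to
  the apex (the choice matches the outward walk that computes it; any
  fixed rule would do). The search window is the whole signal — no
  truncation.
* **Width.** At evaluation height $y_i - r\,P_i$, with $r \in [0, 1]$ and
  default $r = 0.5$ (width at half prominence, the common convention for
  prominence-based detectors), the crossings on each side are located by
  linear interpolation between adjacent samples, bounded by the bases.
  Width is reported both in samples — the unit in which the detection
  threshold is expressed — and in minutes via the retention-time grid.
* **Area.** The trapezoidal integral between the bases minus the
  trapezoidal integral of the chord joining the base points, clipped at
  zero. The chord subtraction makes area invariant to adding a constant to
  the signal, so a drifting baseline does not leak into areas.

A peak is retained when $P_i \ge 3000$ intensity units **and** width
$\ge 8$ samples. These defaults are the working point at which a breath
total-ion signal yields on the order of 100–150 peaks; both are exposed as
parameters (the useful prominence range is roughly 3000–10 000, and widths
much below 7–8 samples are noise-dominated at the default sampling rate).
Width filtering is at `>= 8` samples; since interpolated widths are
continuous, a strict `> 7` variant would differ only on a measure-zero set.

All primitives are implemented in the package and cross-checked in the test
suite against an exhaustive contour-search oracle written independently
from the definitions (and, on one fixture, against an external reference
detector); the oracle is never the implementation.

## Filtering, QC and group comparison

**Moving average.** The only smoothing used is a centred moving average
with the *shrink* edge rule (the window truncates symmetrically at the
edges), which keeps the output length equal to the input and makes window
1 the identity. The default trend window of 301 samples (~1.5 min at the
default 0.005-min sampling interval) is far wider than any single peak, so
filtered curves show the slow intensity envelope rather than individual
compounds. The filter is linear, so filtering each sample and then
averaging a group equals filtering the group mean — asserted to numerical
precision in the tests.

**Signal-to-noise QC.** Failed measurements (leaky sampling, lost sorbent
loading) show as signals with little structure above noise. The estimator
avoids peak detection entirely: noise is
$\hat\sigma = 1.4826\,\mathrm{med}\lvert\Delta y\rvert / \sqrt 2$ (the MAD
of first differences, insensitive to peaks and drift), signal is
$p_{95}(y) - \mathrm{median}(y)$, and samples with
$\mathrm{SNR} < 5$ are flagged, never deleted. The threshold of 5 is a
conventional detection floor and is configurable; a noiseless signal gets
$+\infty$ and always passes. On pure Gaussian noise the statistic
concentrates near $z_{0.95} \approx 1.64$, an order of magnitude below the
threshold of a real signal, which on the default simulation sits above 30.

**Common grid and means.** Samples are linearly interpolated onto a common
grid spanning the latest start to the earliest end of the passing samples,
stepped at the median per-sample sampling interval — interpolation only,
never extrapolation. Per condition, the mean signal is the pointwise
arithmetic mean of the resampled (optionally per-sample filtered) signals.
Averaging after interpolation (rather than before) is a documented choice;
with a shared instrument method the grids differ negligibly and the two
orders coincide.

**Windows.** `early` is $[0, 4)$ min, `mid` is $[16, 19]$ min, `late` is
$(30, \text{end}]$ — half-open or closed exactly as the range descriptions
imply. Per condition and window the summary reports the mean intensity and
a baseline estimate, the 10th percentile of the mean signal within the
window: "baseline" in this context means the level the signal rides on, and
a low quantile estimates it robustly in the presence of peaks without a
separate baseline-correction stage (deliberately absent: baseline elevation
is part of the effect of interest, not a nuisance). A consistency invariant
— window statistics recompute exactly from the stored mean signals — is
asserted in the tests.

## The synthetic cohort generator

No raw chromatograms are publicly deposited for studies of this design, so
the package ships a generator whose outputs stand in for instrument data in
every test. A simulated signal is

$$y(t) = b_0 + b_1 t + \sum_k h_k\, g_k(t) + \varepsilon(t),$$

with $g_k$ a unit-height Gaussian (optionally exponentially modified, since
real GC peaks tail) at apex $t_k$ with width $\sigma_k$, and
$\varepsilon$ i.i.d. Gaussian noise. Every draw is a pure function of
(profile, seed); the global RNG stream is never touched.

The default preset emulates the study conditions the pipeline is built
for:

* 45-min run at $dt = 0.005$ min (0.3-s scans, 9001 points). The
  nominal temperature program of such methods is shorter, but the late
  window extends past 30 min, so the preset uses a 45-min acquisition.
  At this $dt$, the 8-sample width threshold corresponds to ≈ 2.4 s — a
  plausible capillary-GC peak width.
* A frozen library of 125 peaks over 0.5–44 min — near-regular spacing
  (≥ ~0.27 min) with jitter, log-normal heights truncated below at 4500
  intensity units, widths $\sigma \in [0.025, 0.06]$ min. The library is
  drawn once inside the constructor from a fixed internal seed and is
  therefore a package constant: every peak clears both detection
  thresholds by a comfortable margin (width at half prominence ≥ ~10
  samples), so the detected count stays in the 100–150 band across noise
  seeds rather than straddling a threshold.
* Baseline 2000 + 20·t, noise sd 300 — one tenth of the prominence
  threshold, a realistic working ratio for these detectors.
* Cohort of 16 subjects × 3 conditions. Subject-level effects — apex
  jitter (sd 0.02 min) and log-normal height multipliers (CV 0.2, mean 1)
  — are drawn once per subject and shared across that subject's three
  samples, reproducing the repeated-measures design in which
  within-subject contrasts cancel between-subject variation.
* Exposure effects are multiplicative on peak heights and additive on the
  baseline, per window, because exposure changes both signal intensity
  and baseline level: B applies factors (1.25, 1.8, 1.6) and elevations
  (150, 600, 450) in (early, mid, late); C is configured midway between A
  and B (factors 1.1, 1.4, 1.3; elevations halved), matching a 2-h
  washout; A is pinned to factor 1 / elevation 0 as the reference, and a
  null configuration (all factors 1) is available for negative controls.
  The strongest effect sits in the mid window, where chlorination-related
  semi-volatiles elute. Elevations enter as boxcars over the windows —
  adequate for window-level summaries, though the resulting step edges
  are sharper than a real baseline shift.

What the generator does **not** emulate: a mass-spectral ($m/z$)
dimension, retention-time drift between runs, heteroscedastic or
correlated detector noise, co-elution structure beyond what random spacing
produces, and any specific chemistry of individual compounds. Tests passing
on these simulations therefore validate the *algorithms* — detection
correctness, feature geometry, effect recovery in the configured direction
— not instrument-specific behaviour on real data.

## Numerical choices and degenerate inputs

* Retention times must be strictly increasing, in minutes; files whose
  last retention time exceeds 120 are rejected as probably seconds unless
  converted explicitly. The relative-intensity column is validated but
  never used in computation — absolute intensity is authoritative.
* Signals shorter than 3 samples have no interior maxima (empty result,
  not an error); a flat signal detects nothing; `rel_height = 0` gives
  zero width at the apex, `rel_height = 1` the width at base level.
* Peak-table CSVs are written at 12 significant digits, so a
  write-then-read round trip is the identity to that precision; profile
  YAMLs round-trip at 15.
* The per-peak Gaussian is evaluated within ±8σ of its apex (plus 8τ for
  tailed peaks); beyond that the density is below 10⁻¹⁴ of the height, so
  truncation is invisible even to the 0.1 % mass-conservation check.
* Study-level randomness derives from one master seed: subject effects
  and per-sample noise seeds are drawn in a single fixed-order seeded
  block, so any sample is reproducible independently and the pipeline's
  artifact set is byte-identical under a repeated (config, seed).

## Problem sizes in the tests

Module tests run on a reduced profile (8-min run, 10 peaks, 3 subjects);
the calibration, recovery and group-effect checks run on the full default
preset — 10 single-chromatogram seeds for the peak-count band, 10 study
seeds for effect direction, 20 for the null control, and 1000 random short
signals for exact oracle equivalence of prominence, bases and width.

## Known limitations

* Overlapping peaks are not deconvolved; a shoulder below the prominence
  threshold merges into its neighbour's area between that peak's bases.
* The common grid assumes the samples share a retention span; strongly
  misaligned runs would shrink it (retention alignment is out of scope).
* The SNR statistic assumes noise dominates scan-to-scan differences; for
  heavily smoothed (already filtered) inputs it would overestimate SNR.
* Group comparison is descriptive — means, baselines and difference
  curves per window; no inferential statistics are attached.
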