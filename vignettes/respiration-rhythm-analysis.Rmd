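---
title: "Analysing respiration-entrained rhythms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing respiration-entrained rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prr)
```

## The problem this package addresses

During quiet immobility, nasal breathing in mice is remarkably regular
(~3.5 Hz), and the prefrontal local field potential (LFP) carries a slow
1–5 Hz oscillation entrained to it — a respiration rhythm that spectrally
overlaps the classical theta band's lower edge and must be distinguished
from it. Three questions drive the analyses implemented here:

1. **Is the slow LFP rhythm respiration-entrained?** Answered by multitaper
   power spectra (with 1/f compensation) and magnitude-squared coherence
   between the LFP and the nasal airflow signal.
2. **How does the slow rhythm relate to faster oscillations?** Via n:m
   phase–phase coupling against theta (6–12 Hz), and via phase–amplitude
   coupling (PAC) of gamma (30–150 Hz) amplitude by slow-rhythm phase.
3. **Does it organize spiking?** Via circular statistics on the rhythm
   phase at each spike time, per unit, separately for putative pyramidal
   cells (PYR) and interneurons (IN).

Because the recordings such analyses were developed on are not publicly
available, the package pairs every estimator with a synthetic-session
generator whose ground truth is known exactly, so each stage is validated
by construction–recovery rather than by eye.

## Signal primitives and conventions

* **z-scoring.** Every LFP is converted to a z-score (subtract mean, divide
  by SD) before analysis. z-scoring is per session; the session is the unit
  of normalization and this is recorded in pipeline metadata.
* **Filtering.** All band-limiting uses a 2nd-order Butterworth band-pass
  applied forward and backward (`filtfilt`), giving zero net phase shift.
  Note that two passes square the magnitude response: a tone at 3.5 Hz in
  the 1–5 Hz band retains ≈93% of its amplitude, not 100%. This is a
  property of the specified filter, shared by any pipeline using the same
  design, and is irrelevant to phase estimates.
* **Phase and amplitude.** Instantaneous phase and envelope come from the
  FFT-based analytic signal (Hilbert transform). The phase convention is
  **0 at the oscillation peak, ±π at the troughs**, everywhere: in LFP
  phases, spike-phase histograms and PAC distributions.
* **Filter-then-mask.** Filters and transforms are always applied to the
  full trace first; epoch masks are applied afterwards. The pipeline trims
  1 s from each end of the recording (filter edge transients decay well
  within this) and drops epochs shorter than 2 s — two slow-rhythm cycles
  at the 1 Hz band edge, below which phase estimates are not meaningful.
* **Phase bins.** All phase histograms use 18 bins of 20°, edges at
  −π + k·π/9.
* **Spike-phase lookup.** Spike times (sampled at 30 kHz upstream) are
  matched to the nearest LFP sample; signals are never resampled for phase
  lookup, avoiding interpolation bias.

## Spectral estimation

Power spectral density is computed on disjoint 5 s chunks inside the
analysis epochs (chunks never span epoch boundaries) with Slepian tapers
and averaged. A spectral bandwidth of 1 Hz on 5 s chunks corresponds to a
time–bandwidth product NW = 2.5, and ⌊2·NW⌋ − 1 = 4 tapers are used. For
chunks longer than 1024 samples the tapers are solved at length 1024 from
the standard symmetric tridiagonal eigenproblem and spline-interpolated,
which preserves their shape to high accuracy. Spectra are multiplied by
frequency (`normalize_1f()`) to compensate the 1/f decay before band peaks
are read out; peak ties break to the lower frequency for determinism. Two
caveats worth knowing: a pure tone is smeared over the ±0.5 Hz taper
bandwidth, and the frequency normalization tilts that smeared top slightly
towards higher frequencies — peak-location accuracy is therefore the
analysis bandwidth, not the raw FFT bin, for line-like spectra.

Coherence uses Welch averaging with windows of 0.5·fs samples zero-padded
to 10·fs points, Hann-tapered, with 50% overlap (the overlap is a
conventional choice, recorded in the output metadata).

## n:m phase–phase coupling

With φ_PRR and φ_θ the Hilbert phases of the 1–5 and 6–12 Hz filtered LFP,
the slow phase is accelerated by an integer factor m = 1…25 and

R_n:m(m) = | ⟨ exp{ i (φ_θ(t) − m·φ_PRR(t)) } ⟩ |

is computed on 25 segments of 10 s with uniformly random start positions
inside the immobility epochs (sampled without replacement when enough
distinct positions exist) and averaged. R_n:m is 0 for unrelated phases
and 1 for perfect locking; 2:1 locking peaks at m = 2. The segments are
constrained to immobility epochs, consistent with restricting all coupling
analyses to immobility; an `epochs = NULL` call lifts the constraint.

The surrogate control circularly shifts the slow-phase series by a random
offset uniform in 5–10 s and repeats the computation on the same segment
positions. A circular (wrap-around) shift preserves the sample count and
each series' own statistics — the standard time-shift surrogate. One
matched surrogate per session is the default, mirroring a paired design;
`n_surrogates > 1` averages several independent shifts as an extension.
The paired comparison (`compare_rnm()`) tests R against the surrogate at
m* = argmax of the group-mean profile with a two-tailed paired t-test.

## Phase–amplitude coupling

The mean gamma envelope is collected in the 18 phase bins, normalized to
sum 1, and compared to the uniform distribution by Kullback–Leibler
distance; dividing by log 18 yields the modulation index MI ∈ [0, 1]
(0 = flat envelope, 1 = all envelope mass in one bin). Bins with zero mass
contribute zero to the sum (the x·log x → 0 limit); since the reference is
uniform, the distance stays finite. MI is invariant to envelope rescaling
and phase rotation, and carries a positive small-sample bias — within-
condition comparisons should use equal window counts.

The comodulogram scans slow bands of 1 Hz bandwidth centred 2–10 Hz
against fast bands of 10 Hz bandwidth centred 30–150 Hz, computing MI in
non-overlapping 4 s windows inside the epochs and averaging window MIs
(the literal windowed-average reading; pooling the distributions before
one MI is available through `modulation_index()` directly). Headline
single-band MIs use the 1–5 Hz filter for the slow phase (the comodulogram
grid starts at 2 Hz; both conventions are emitted) and the 80–100 Hz
envelope for gamma. One methodological caveat the comodulogram inherits
from its bandwidth choices: a 10 Hz-wide amplitude filter transmits
envelope sidebands only ±5 Hz from the carrier, so modulation *by phase
frequencies above ~5 Hz* (e.g. 8 Hz theta) is attenuated at the default
bandwidth; `amp_bw_hz` widens it when theta-driven PAC is the target.

The preferred coupling phase is the circular mean of bin centres weighted
by the normalized envelope; when the weighted resultant is < 1e−6 (flat or
antipodally symmetric distributions) the phase is flagged undefined.

## Theta-rich epochs

The trace is theta-filtered (6–12 Hz), the rms is computed in a sliding
0.5 s window with 50% overlap (≥3 theta cycles per window; the window is a
package choice recorded in metadata), and the threshold is mean + 2·SD of
the rms series. Each supra-threshold rms value marks its window centre
± half a hop; adjacent marks merge when separated by less than the window
length. Because the threshold adapts to the series' own statistics, a
stationary trace — even one of pure strong theta — yields only the tail
fraction (a few %), while brief strong bursts are detected nearly in full:
with 1% of a 600 s trace occupied by 5× amplitude bursts, the burst
windows inflate the SD, the threshold rises above the baseline
fluctuations, and the detected time stays below 2% of the recording.

## Single units

Cell types are classified from the mean waveform: the trough is the global
minimum (required to be negative-going, away from the edges, and to
dominate the positive excursion — otherwise the unit is flagged
unclassifiable); half-duration is the width of the trough lobe at half
depth (linearly interpolated); trough-to-peak time runs from the trough to
the maximum after it, both refined to sub-sample precision by parabolic
interpolation after light 1:2:1 smoothing. Using the maximum after the
trough rather than the first local maximum is a deliberate robustness
choice: under a few percent of waveform noise the first local maximum is
frequently a noise wiggle on the rising flank, while the two definitions
coincide on clean biphasic waveforms. A unit is IN when trough-to-peak
< 0.25 ms **and** half-duration < 0.35 ms, else PYR — thresholds at the
midpoints between the reported group means (IN 0.20/0.25 ms vs PYR
0.31/0.47 ms), configurable.

Spike-phase coupling per unit and rhythm (slow rhythm, theta, and the
1–10 Hz filtered respiration trace) uses the mean resultant length R, the
circular mean, and Rayleigh's test with the standard approximation
p = exp(√(1 + 4n + 4(n² − (nR)²)) − (1 + 2n)). Units with fewer than 10
spikes inside the epochs are flagged excluded rather than tested.
Population summaries report per-class entrainment fractions, cross-rhythm
overlap among significant units, chi-square tests of PYR vs IN proportions
at a Bonferroni-adjusted critical p (α divided by the number of rhythm
comparisons), and 18-bin histograms of preferred phases.

## The synthetic-session generator

`generate_session()` composes, from one seed (bit-identical regeneration
is a tested invariant):

* **Respiration** — cycle periods i.i.d. gamma with mean 1/3.5 s and CV
  0.1 (gamma keeps periods positive and smooth; the CV is a realistic
  immobility value — breathing during immobility is stable), phase
  integrated continuously, trace = cos(phase) so inspiration deflects
  positive.
* **LFP** — (a) slow component: respiration phase shifted by a free lag
  parameter (default 0; the true airflow-to-LFP lag is not asserted
  anywhere and is exposed as a parameter), amplitude 1 z-unit;
  (b) theta at exactly 2 cycles per slow cycle with one von Mises phase
  deviate (κ = 4 by default — chosen because it maps onto the analytic
  mean resultant I₁(κ)/I₀(κ) used as an oracle) per slow cycle, linearly
  interpolated, amplitude 0.6; (c) gamma: 80–100 Hz filtered noise carrier
  with envelope 1 + d·cos(φ_slow − φ_pref), d = 0.5 at the slow-rhythm
  peak by default, amplitude 0.4; (d) 1/f^1.5 Gaussian background of unit
  SD; the sum is z-scored.
* **Spike trains** — inhomogeneous Bernoulli thinning of intensity
  ∝ exp{κ·cos(φ(t) − φ_pref)} normalized to the target rate, pruned to a
  2 ms absolute refractory period (matching the >1 ms sorting criterion
  with margin). PYR units average 1.7 Hz, IN units 9.4 Hz (log-normal
  spread 0.2); 26% of PYR and 58% of IN are entrained by the slow rhythm,
  21%/35% by theta (κ = 1.5), with class-specific preferred phases (−0.89
  rad for slow-rhythm PYR, 1.34 rad for IN).
* **Waveforms** — a negative Gaussian trough plus positive after-peak
  lobe, calibrated by fixed-point iteration against the classifier's own
  metric definitions so the measured half-duration and trough-to-peak
  equal the class targets exactly; 2% Gaussian waveform noise by default.
* **Immobility** — epochs tiling 60% of the session in 30 s blocks
  (fraction 1 covers the whole session).

What the generator does **not** emulate: non-sinusoidal waveform shape of
the slow rhythm, movement and chewing artifacts, non-stationary breathing
(state transitions), electrode drift, spike-sorting contamination, and
correlated noise across units. Passing recovery tests therefore shows the
estimators are correct under the stated statistical structure, not that
real recordings meet that structure.

## Numerical and testing choices

* Degenerate inputs error early: constant signals (z-score, theta rms),
  all-zero signals (analytic transform), zero total envelope (MI), empty
  epoch sets, bands outside Nyquist or spectrum support.
* A zero-difference paired R_n:m comparison returns p = 1 rather than a
  NaN from the t statistic; a class-proportion table with no outcome
  variation returns p = 1.
* Seeded stages (segment placement, surrogate shifts, all generators)
  restore the caller's RNG stream, so seeds compose without side effects.
* Test problem sizes are chosen so the full suite completes in a few
  minutes on one core: sessions of 20–300 s, sampling rates of 250–1000 Hz
  and 10–50 seed replicates per calibration check; the statistical
  tolerances in the tests were derived from the corresponding analytic
  values or null simulations at those sizes.

## Known limitations

* The comodulogram's amplitude-bandwidth caveat above; the default mirrors
  the published grid, not an optimal detector for fast modulators.
* The Rayleigh p approximation is accurate for n ≳ 10 (the exclusion
  threshold) but not exact for very small n.
* MI values are averages over 4 s windows and carry the window-count bias
  noted above; comparisons across conditions with different amounts of
  data should pool equal window counts.
* The multitaper implementation interpolates tapers for chunks longer than
  1024 samples; concentration loss is negligible for the bandwidths used
  here but would matter for NW ≫ 5.
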