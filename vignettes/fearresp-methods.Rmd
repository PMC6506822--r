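---
title: "Methods: respiration-entrained oscillations, USV and behaviour in fearresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration-entrained oscillations, USV and behaviour in fearresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`fearresp` analyses four synchronized streams from fear-conditioned
rats during 60-s post-shock windows: a plethysmograph respiration trace
(~1 kHz), one or more LFP channels (1 kHz, interpretable up to
~80–100 Hz given typical hardware filtering), ultrasonic audio
(214285 Hz) or a precomputed call table, and video frames (25 Hz) or a
precomputed motion trace.  The underlying physiological model has three
ingredients:

1. **State-dependent breathing.**  Respiratory rate depends on the
   behavioural state: about 6.3 breaths/s during silent escape,
   2.8 during silent freezing, dropping to roughly 1.4 and 1 breaths/s
   when 22-kHz calls are emitted (calls occur during expiration and
   lengthen it dramatically).
2. **Respiration-entrained slow oscillation.**  During silent freezing
   the dominant delta-band LFP frequency tracks the instantaneous
   respiratory frequency; during calling this coupling is lost.  Theta
   sits at a fixed 6–7 Hz regardless of breathing.
3. **Phase-amplitude modulation.**  Beta and gamma amplitude are
   modulated within the respiratory cycle, with a state-dependent
   preferred phase (inspiration-dominant in silent states, shifted into
   expiration under USV).

All times are seconds from session start on one clock; all event
intervals are half-open `[onset, offset)`.

# Pipeline stages and key parameters

## Respiratory cycle detection

`detect_cycles()` smooths the trace with a zero-phase moving average
(default 25 ms — long enough to kill sensor ripple, an order of
magnitude shorter than the fastest plausible cycle of 100 ms), removes
a 2-s centred running-mean baseline, and detects baseline crossings
with a hysteresis of 5% of the interquartile range.  Inspiration is
the negative-going limb by default (`sign_convention = "neg"`, the
common plethysmograph convention; configurable).  Crossing times are
refined by linear interpolation between the bracketing samples.
Cycles shorter than `min_cycle_s = 0.1` s (a 10-Hz ceiling, above the
sniffing range in this paradigm) are merged into their predecessor;
incomplete first/last cycles are discarded.

*Why a running mean and not a running median:* with inspiration
occupying ~40% of the cycle, the median of a zero-mean breathing
waveform sits well above zero (about +0.18 for the unit-amplitude
template used here), which would bias every crossing by 8–25 ms
depending on the rate.  The running mean has no such duty-cycle bias
and still removes slow drift.  The smoothing and baseline filters are
applied circularly; this preserves the mean exactly and avoids
shrinking-window bias at the edges, at the cost of wrapping a few
samples of the trace ends — immaterial for traces much longer than the
2-s baseline window.

Momentary respiratory frequency is `1/duration`, held constant across
the cycle (`instantaneous_frequency()`, default 4-ms step to share a
clock with the coupling analysis); `respiration_pdf()` normalizes a
histogram of those samples with 0.33-Hz bins anchored at 0 Hz.

## Freezing scoring

`frame_motion()` subtracts consecutive frames and binarizes the
absolute difference at a gray threshold; the white-pixel count per
40-ms bin (two frames at 25 Hz) is the motion trace.  When no
threshold is given it is calibrated as 3 × the robust spread (`mad`)
of the *signed* difference pixels, which tracks the sensor-noise floor
because moving-object pixels are a small minority.  `score_freezing()`
turns maximal runs of zero-count bins into freezing when they last at
least 1 s; shorter zero runs are absorbed into the surrounding escape
so that the two states tile the window (in the post-shock minute the
animal only freezes or escapes).  Dropping rather than splitting
sub-second candidates keeps the tiling exact while honouring the
stable-freezing minimum.

## USV detection and blocks

`compute_spectrogram()` uses a 512-point FFT, 87.5% overlap (64-sample
hop) and a flat-top window, giving 418.5 Hz ≈ 419 Hz frequency spacing
and 0.2987 ms ≈ 0.29 ms hop at 214285 Hz.  `track_whistles()` marks a
frame voiced when its 18–32 kHz peak exceeds −20 dB relative to the
session-wide spectrogram maximum (the reference for the threshold is a
package choice; vendor software leaves it unstated), merges voiced
runs separated by less than the 0.02-s hold time, and drops merged
runs shorter than 0.01 s.  Call features are the frame span, the
in-band peak frequency and the peak level.

`group_blocks()` merges successive calls whose offset-to-onset gap is
below 1 s.  A gap of *exactly* 1 s starts a new block — the boundary
case is undefined in the field's verbal rule ("less than 1 s" within
blocks vs "exceeded 1 s" between), and ≥ 1 s as a break is recorded
here as the package's convention.  Downstream, a block's bounding
interval counts as USV time, including its sub-second internal gaps.

## Category segmentation and artifact screening

`intersect_categories()` forms the union of block intervals (USV mask),
takes its complement as silent, and labels every maximal interval of
constant (vocal state, behaviour) pair; candidates shorter than 1 s are
dropped and their time excluded from all downstream averages ("longer
than 1 s" is read boundary-inclusive).  `screen_artifacts()` flags
samples at or beyond full scale (default: 1.05 × the 99.9th amplitude
percentile, an automated proxy for the amplifier rail that visual
screening would identify directly) or inside constant runs ≥ 0.5 s;
a trial is excluded above 5 artifact-seconds per 60-s window, a site
when more than 5 of 10 trials fail.

## Morlet scalogram and band power

`morlet_scalogram()` convolves the trace with 6-cycle complex Morlet
atoms (the classic time-frequency trade-off) on a grid of 0.1 Hz below
15 Hz and 0.5 Hz above.  The analytic frequency-domain filter has peak
gain 2, so a unit-amplitude tone yields amplitude 1 at its own
frequency — convenient for calibration tests.  Samples within one
wavelet half-width (2σ_t) of the trace edges are inside the cone of
influence and excluded from averages.  "Power" is the squared modulus;
mean spectra are exposed both as amplitude (what PSD figures plot) and
power (what band means use).  Bands are half-open — delta `[0,5)`,
theta `[5,15)`, beta `[15,40)`, gamma `[40,80)` Hz — so shared
boundaries are counted once, in the upper band.  Category averages are
duration-weighted (pooled samples), hence invariant to splitting a
segment.

## Frequency–frequency coupling

Classical coherence is inappropriate because the respiratory signal is
far from sinusoidal, especially during calls.  Instead
`dominant_lfp_frequency()` extracts, every 4 ms, the frequency of the
scalogram maximum in 0–15 Hz (ties break toward the lower frequency;
all-zero columns are flagged and dropped pairwise), and
`coupling_histogram()` bins the (respiratory, LFP) frequency pairs on
a 0.33-Hz grid on both axes (reusing the respiration-PDF bin; no 2-D
bin width is standard), normalized to total mass 1.
`diagonal_coupling_index()` sums the mass within ±0.5 Hz of the
identity line and subtracts the same sum under the product of the
marginals, clipping to `[0, 1]`.  Subtracting the independence
expectation matters: a nearly constant breathing rate concentrates
both marginals in the same bins and would otherwise fake coupling.
Conversely the index is only informative when the breathing rate
explores a range of bins — one reason the simulator gives the rate a
slow drift (below).

## Cycle-frequency scalogram

`cycle_frequency_scalogram()` segments the scalogram at detected
inspiration/expiration onsets and stretches each phase by per-frequency
linear interpolation onto a fixed template: inspiration `[0, 0.4)`,
expiration `[0.4, 1)`, forty bins of 0.025, interpolated at bin
centres (centres avoid the half-bin bias of edge placement).  The 0.4
transition is the average inspiratory fraction over cycles and is
configurable.  Cycles are used only if they lie entirely inside one
segment and both phases contain at least two scalogram samples; the
average is cycle-count-weighted.  Because the phase template's 0.4/0.6
split matches the inspiratory duty cycle, the phase-mean of the map
equals the time-mean power over the same cycles (conserved to within
interpolation error; verified at 5%).  `band_max_power_curve()` takes
the per-phase maximum over a band's rows, the standard way to read off
the preferred phase.

# The synthetic-session generator

`simulate_session()` produces all modalities from one seed (R's
default Mersenne-Twister; each modality uses a fixed offset of the seed
so modalities can also be simulated independently and reproducibly).

- **Respiration**: concatenated cycles, each a negative half-sine
  inspiration limb (40% of the cycle) followed by a positive expiration
  limb; zero at every limb boundary, so the waveform is continuous and
  crossings are transversal.  Cycle durations are drawn around the
  state's nominal rate with 5% cycle-to-cycle jitter, and the rate
  itself follows an AR(1) drift on the log scale (coefficient 0.9, step
  SD 0.04, stationary SD ≈ 9%).  The drift reflects the slow waxing and
  waning of breathing rate in real animals; it also makes the coupling
  analysis well-posed, since frequency–frequency covariation is
  undefined when the rate never leaves one histogram bin.
- **LFP**: delta whose instantaneous frequency equals the respiratory
  frequency in `delta_locked_states` (default: silent freezing only)
  and is fixed at 3.5 Hz elsewhere; theta at 6.5 Hz; beta (25 Hz) and
  gamma (55 Hz) carriers with raised-cosine phase envelopes
  `1 − d + d·(1 + cos 2π(φ − φ₀))/2` at state-dependent preferred
  phase φ₀ and depth d; 1/f background noise.  Envelopes are
  normalized to unit RMS so that band power depends only on the
  configured per-state amplitudes, keeping "injected contrast" and
  "measured band-power contrast" on the same scale regardless of
  modulation depth.  Default amplitudes encode the qualitative
  contrasts of interest: delta higher in freezing and under USV, theta
  higher in escape and reduced under USV, beta and gamma raised under
  USV, gamma higher in escape.
- **USV audio**: each cycle of a USV state carries a call with
  probability 0.9; calls are 22-kHz constant-carrier bursts with 2-ms
  cosine ramps, onset shortly after expiration onset and duration
  truncated to fit the expiration limb — so every true call interval
  lies inside a true expiration interval by construction.  Call-rate
  and gap distributions are free parameters, not claims about real
  call statistics.
- **Video**: a bright 8×8 blob on a dark background, stationary during
  freezing, translating 3 px/frame with a slowly wandering direction
  (wrapping at the frame edges) during escape.  Sensor noise is
  *uniform* and therefore bounded: frame differences during freezing
  can never exceed twice the noise half-width, so the exact "absence
  of white pixels" rule is attainable, as it is with a real camera's
  quantized output.

What the generator does **not** emulate: acoustic realism of calls
(frequency modulation, harmonics), plethysmograph physics (sighs,
apneas, movement artifacts on the pressure trace), non-stationary
electrode noise, occlusions or lighting changes in video, and any
coupling mechanism beyond the injected ones.  Passing recovery tests
therefore demonstrates the correctness of the analysis path, not the
robustness of the detectors to every real-world nuisance.

## Evaluating recovery where the injection is defined

Scheduled USV states emit calls probabilistically, so a scheduled USV
state occasionally contains a silent stretch longer than 1 s; the
segmentation correctly labels it silent although the generator injected
USV-state amplitudes there.  Recovery analyses therefore restrict
realized category segments to times where the realized category
coincides with the scheduled state.  Without this restriction a small
injected contrast between two categories (e.g. 6% in amplitude) can be
masked by cross-state dilution — a property of the evaluation, not of
the pipeline.

# Numerical choices and degenerate inputs

- Interval semantics are half-open everywhere; tiling checks use a
  1e-6-s tolerance.
- A flat respiration trace (no crossings) returns an empty cycle list
  with a warning rather than an error; an all-zero scalogram column
  yields a flagged (NA) dominant frequency, dropped pairwise.
- Unordered call tables are sorted with a warning; empty call tables
  propagate as empty block tables and purely silent segmentations.
- The dominant-frequency argmax breaks ties toward the lower
  frequency; histogram bins are anchored at 0 Hz.
- Simulation seeds: a session's modalities use `seed`, `seed+1`,
  `seed+2`, `seed+3` (respiration, LFP, audio, video).

# Problem sizes

The validation suite uses 120-s four-state sessions (40 s of each
freezing state, 20 s of each escape state) and 20 seeded replicates
for parameter recovery; 60 s of ultrasonic audio for the call
round-trip; 1000 random fixtures each for the block-grouping and
segmentation oracle equivalences; and 10–60-s single-state sessions
for unit-level checks.  These sizes give stable modes and medians
while keeping a full run on one CPU in minutes.

# Known limitations

- The whistle tracker assumes tonal 22-kHz calls; strongly
  frequency-modulated or overlapping calls would need a contour
  tracker.
- The artifact screen's full-scale and flat-run defaults are automated
  proxies for what is usually a visual screening step; they should be
  set from amplifier specifications when known.
- The cycle-frequency scalogram averages raw power across cycles; an
  optional per-cycle normalization is a reasonable extension when
  comparing animals with very different absolute power.
- Cross-band leakage (a strong delta rhythm contributing to the lower
  theta rows, beta sidebands reaching the lower gamma rows) is inherent
  to wavelet band means; the half-open band conventions bound but do
  not remove it.
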