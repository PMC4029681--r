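---
title: "Wheeze detection from overlapped STFT segments: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wheeze detection from overlapped STFT segments: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheezer)
```

## The signal model

Normal respiratory sound is cyclostationary band-limited noise: each
respiratory cycle consists of an inspiratory phase, an expiratory phase and
an inter-respiratory pause, with inspiration typically louder and longer
than expiration. Over the lungs most of the energy sits in the 100–250 Hz
band; tracheal sounds extend to about 1 kHz. Asthmatic wheezing is a
continuous tonal sound superimposed on this noise: one to a few harmonic
components between roughly 100 and 1,500 Hz whose amplitudes and
instantaneous frequencies drift slowly, lasting from tens of milliseconds
to several seconds.

Segments short enough to be locally stationary make the wheeze visible in
the short-time Fourier transform: the windowed harmonic smears into a
"spectral crest" — a flattened band of elevated magnitude around a local
maximum — that stays put (within a few bins) across successive segments,
while noise maxima jump around. Everything in this package is built on
that contrast.

## The analysis grid

Recordings are resampled to 8 kHz (polyphase rational resampling via the
`signal` package), downmixed to mono, and peak-normalized — the absolute
gain of a recording chain is device-specific, so thresholds are trained on
the normalized scale. Analysis segments are `N = 512` samples (64 ms) with
50% overlap, Hamming-windowed (periodic variant, the STFT convention for
overlapped analysis); the hop is therefore 32 ms. The one-sided spectrum
is restricted to an analysis band of 60–950 Hz: the lower edge excludes
heart sounds, which concentrate below 60 Hz, and at this grid the band
spans `ceiling(60/15.625) = 4` through `floor(950/15.625) = 60`, i.e. the
characteristic 57 bins used throughout the operation-count model. All of
these are `wheeze_config()` defaults and can be overridden.

## Per-segment features

* **Segment energy** `E = sum(P[k])` over the band; its extrema over a
  ring buffer of the last `M_E` segments drive pause detection. `M_E`
  defaults to 156 segments (≈5 s at the 32 ms hop), enough to always
  cover at least one full respiratory cycle so that the stored extrema
  bracket both a breath and a pause.
* **Tonality index.** Each band bin's amplitude and phase are linearly
  extrapolated from the two preceding segments
  (`A_hat = 2A[m-1] - A[m-2]`, same for phase); the normalized prediction
  error `W = sqrt((Re-Re_hat)^2 + (Im-Im_hat)^2) / (A + |A_hat|)` weights
  the power spectrum, and `T = log2((E_w + eps)/(E + eps))`. A stationary
  tone is perfectly predicted (`W -> 0`, `T` strongly negative); noise is
  unpredictable (`W ~ 1`, `T ~ 0`). Phase wrapping needs no special
  handling: the extrapolated phase enters only through `cos`/`sin`, which
  are invariant to the 2π ambiguity of principal values.
* **Spectral peaks** are strict local maxima of the band power spectrum
  (band-edge bins excluded). **Peak entropy** is the Shannon entropy (in
  bits) of the peak magnitudes normalized to a probability mass function:
  at most `log2(N_p)` (equal peaks, noise-like), dropping toward 0 as
  energy clusters into few peaks (wheeze). The **entropy ratio** between
  successive segments spikes at wheeze onsets and offsets.
* **Crest models.** Around each peak, the moment model accepts a crest iff
  `P_peak > C_m * mean + C_s * sd` over the `B_crest + 1` surrounding bins
  (population standard deviation, matching fixed-point DSP practice). The
  energy model compares the crest-band energy against two concentric
  *annular* surroundings (crest bins excluded):
  `E_crest/E_narrow > C_narrow` and `E_crest/E_wide > C_wide`. The annular
  reading is forced by the trained thresholds exceeding 1 — with nested
  bands `E_crest/E_narrow <= 1` always, and no threshold above 1 could
  ever accept.
* **Crest tracks.** Crests are matched greedily (ascending frequency) to
  the nearest live track, ties to the lower-frequency track, with a
  matching gate of `C_cont[1]` bins — a crest farther than the lag-1
  continuity threshold from every live track starts a new track rather
  than teleporting an old one. A matched track's per-lag frequency
  deviations `|k[m] - k[m-j]|` must stay below `C_cont[j]` for all
  `j <= min(M_cont, duration - 1)` to count as continuous.

## The four decision trees

All four share the same root: the **energy gate**. A segment is an
inter-respiratory pause iff `E <= E_min + C_pause (E_max - E_min)` over
the recent energy history; pauses are NORMAL under every algorithm, with
no further feature extraction. Two deliberate refinements of the bare
rule, found necessary when tracing the detectors on synthetic tones:

* Pause detection presumes energy *contrast*. When the history's dynamic
  range is under 3 dB (`E_max <= 2 E_min`) there is no pause to find and
  the gate fails open — otherwise a constant-envelope signal has about
  `C_pause` of its segments spuriously gated by the tiny ripple of the
  windowed tone energy.
* For the tonality detector, the two-segment amplitude/phase history is
  still updated during pause-gated segments (the label stays NORMAL and
  the tonal run resets). Freezing it, as literal early termination would,
  makes the first post-pause predictions extrapolate from stale spectra.

**Algorithms 1 and 2 (crest tracking)** detect crests with the moment or
energy model, require `1 <= N_c <= C_crests` (a dense comb of maxima is
noise, not wheezing; the lower bound admits single-component wheezes), and
fire iff a continuous track's duration lies in
`[M_dur,min, M_dur,max]`. `M_dur,min = M_cont` by construction; `M_dur,max`
defaults to 125 segments (≈4 s, a respiratory cycle). When the count gate
fails, the segment is NORMAL but live tracks are kept frozen: a single
noisy segment pushing `N_c` over the cap must not reset every wheeze
duration (killing tracks there punches `M_cont`-segment holes into
otherwise continuous detections). Tracks still die at pauses and when
unmatched.

**Algorithm 3 (tonality)** marks a segment tonal iff `T < C_T` and fires
while the run length of consecutive tonal segments lies in
`[M_dur,min, M_dur,max]`. The direction is the mathematically forced one:
under the prediction-error construction, predictability drives `T` toward
−∞, so the threshold is negative (default −2, trainable). Reference
fixed-point implementations state the comparison the other way around
under an unstated integer scaling; their printed thresholds (tens of
thousands) are Q-format values and are not usable as floats.

**Algorithm 4 (entropy change)** fires iff
`max(En_ratio, 1/En_ratio) > C_ent`, a two-sided test: entropy drops at a
wheeze onset and recovers at the offset, and a single threshold `C_ent >= 1`
covers both. An undefined ratio (previous entropy ≈ 0, or the previous
segment was a pause) is treated as no-transition. This detector flags
*transitions*, not durations — its positives cluster at annotated wheeze
boundaries, which is exactly what the acceptance suite checks.

## Training and evaluation

`grid_search_train()` exhaustively scores every point of a named threshold
grid (segment-wise, pooled over the training recordings) and selects the
argmax of `SE × SP`, ties resolving to the first point in lexicographic
grid order; the full ROC point cloud is returned for inspection.
`leave_one_out()` trains on all-but-one recording and tests on the
held-out one, pooling confusion counts over folds and reporting
wheeze-recording, normal-recording and overall metrics in both scenarios.
Implementation note: per-recording confusion counts are computed once per
grid point and re-aggregated per fold — algebraically identical to naive
refitting, and what keeps a 26-recording leave-one-out inside a test
suite's runtime.

Scoring conventions: a segment's reference label is the annotation at its
*center* time (annotation resolution is inherently limited by the segment
grid, and the center is the least biased single point); a respiratory
phase is a reference positive iff it overlaps a wheeze interval, and a
predicted positive iff it contains at least one positive segment. A metric
whose denominator is zero is reported as `NA`, never coerced to 0.

## The synthetic generator

`sim_config()`/`generate_recording()` emulate the signal model, not any
particular patient: Gaussian noise shaped by a 4th-order Butterworth
band-pass (default emphasis 100–250 Hz) plus a small broadband floor,
modulated by a raised-cosine phase envelope (defaults: 1.5 s inspiration
at amplitude 1, 1.5 s expiration at 0.5, 1 s pause at 0.03). Wheezes are
sums of 1–3 harmonics with `1/h` roll-off and a linearly drifting
fundamental, scaled so that the delivered SNR — tone power against the
local background power within the wheeze interval — matches the
configuration (verified to ±2 dB by the test suite). Annotations are exact
by construction. `generate_dataset()` derives per-recording seeds from a
master seed; the default draw ranges (f0 200–800 Hz, duration 0.5–1.2 s,
drift ±25 Hz/s, SNR fixed at 15 dB, 2–3 wheezes per positive recording
placed in expiratory phases) define the study conditions used by the
acceptance suite: 13 wheeze + 13 normal recordings of 3 cycles (12 s)
each, ≈9,700 segments in total.

What the generator deliberately does *not* model: patient- and
site-dependent transfer characteristics, heart sounds (below the analysis
band anyway), crackles and other discontinuous adventitious sounds,
amplitude-modulated or polyphonic wheezes with crossing components, and
recording-chain artifacts. Passing the synthetic acceptance bars therefore
demonstrates parameter recovery under the stated signal model — not
clinical-grade accuracy on real patients, for which the reference
accuracies shipped with the package (measured on 26 real recordings)
remain the relevant anchor.

## Numerical choices

All divisions and logarithms are guarded by `eps = 1e-12`; the tonality
index is clamped to ±30 (the all-zero-spectrum case yields exactly 0 by
the guard). The population (1/n) standard deviation is used in the moment
crest model. Crest bands are clipped at the analysis-band edges. Framing
discards trailing samples that do not fill a whole segment
(`floor((len - N)/hop) + 1` segments); resampling uses exact rational
polyphase factors. The operation-count model is exact integer arithmetic
throughout, and each detector's total cost is defined as the sum of its
constituent program blocks — the stated construction of the reference
totals, which also resolves two typesetting inconsistencies in the
printed per-algorithm rows (the crest-continuity additions and the
tonality-branch additions coefficient) in favour of the block sums; the
windowing product appears as its own `N`-multiplication block.

## Parameter summary

| Parameter | Default | Meaning |
|---|---|---|
| `N`, overlap | 512 samples, 50% | 64 ms segments, 32 ms hop at 8 kHz |
| `f_lo`–`f_hi` | 60–950 Hz | analysis band (57 bins) |
| `C_pause`, `M_E` | 0.1, 156 | pause gate fraction and energy history |
| `B_crest` | 6 bins | crest bandwidth (≈94 Hz) |
| `C_m`, `C_s` | 1.5, 1.0 | moment-model coefficients (trainable) |
| `B_narrow`, `B_wide` | 125, 187.5 Hz | annular surroundings (8 / 12 bins) |
| `C_narrow`, `C_wide` | 1.2, 1.5 | energy-ratio thresholds (trainable) |
| `C_crests` | 7 | maximal admissible crest count |
| `M_cont`, `C_cont` | 4, (3,3,3,3) | continuity depth and per-lag limits |
| `M_dur_max` | 125 segments | maximal wheeze duration (≈4 s) |
| `C_T` | −2.0 | tonality threshold (trainable) |
| `C_ent` | 2.0 | entropy-ratio threshold (trainable) |

On `B_narrow`/`B_wide`: the textual reference values of 80 and 120 Hz
contradict their own characteristic bin widths (8 and 12 bins at
15.625 Hz/bin) *and* the nesting precondition `B_crest < B_narrow` once
`B_crest = 6` bins ≈ 94 Hz; the defaults here are the characteristic bin
widths expressed in Hz (125 and 187.5), which satisfy the nesting and
reproduce the published operation counts.

## Known limitations

The detectors are single-channel and threshold-based; no spectral
equalization/detrending preprocessing is applied (the implemented decision
trees do not use it), wavelet or 2D-image denoising of spectrograms is out
of scope, and no statistical classifier (SVM/NN/GMM) is provided. Track
assignment is greedy nearest-neighbour rather than globally optimal —
deterministic and cheap, and adequate for the 1–3 component wheezes of
the signal model, but it can mis-assign crossing components. Cycle counts
for the efficiency metrics are inputs (measured on reference hardware),
never profiled by this package. The floating-point implementation is not a
bit-exact model of 16-bit fixed-point arithmetic; thresholds trained here
do not transfer to Q-format implementations without retraining.
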