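---
title: "Methods: quantifying sedative effects on neonatal EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sedative effects on neonatal EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameter choices and numerical
conventions behind `dexeeg`, in the spirit of a methods supplement: what the
pipeline computes, why each constant has the value it has, and what the
synthetic validation does and does not demonstrate.

## The analysis model

The pipeline treats a recording as a channels × samples matrix in µV with a
drug-administration timestamp `drug_time` (seconds from start). All time
handling is 0-based with half-open intervals `[t0, t1)`, so windows and
epochs tile without overlap or double counting.

Eight derivations are analysed: the four recorded referential channels (F3,
F4, P3, P4; signals are treated as already referenced — no re-referencing is
performed, since the montage records against a common midline reference) and
four bipolar differences (F3−P3, F4−P4 within hemispheres; F3−F4, P3−P4
across). Bipolar derivations are exact sample-wise subtractions, hence
linear in the input.

### Band-pass filtering

The clinical band is 0.2–35 Hz. We filter with the *squared-magnitude*
Butterworth response — a 2nd-order high-pass at 0.2 Hz times a 4th-order
low-pass at 35 Hz — applied in the frequency domain to a reflection-padded
signal. This is the response a forward–backward (zero-phase) filter applies,
evaluated exactly on the FFT grid; it is strictly zero-phase, so burst
onsets used by the synchrony measure are not displaced. One octave outside
the band the attenuation is ≥ 24 dB (measured: ~48 dB at 0.05 Hz and at
60 Hz). Frequency-domain application was chosen over recursive `filtfilt`
because a 0.2 Hz corner at 250 Hz sampling sits at a normalized frequency of
0.0016, where transfer-function recursions are numerically delicate, and
because multi-hour recordings make FFT filtering several-fold faster.

### Artifact handling

Detection operates per derivation on the band-passed signal, at the same
2-s grid the rEEG uses, with three detectors:

| detector | rule | default | rationale |
|---|---|---|---|
| amplitude | any \|x\| above threshold | 500 µV | cortical activity stays far below; movement/pops exceed it |
| high-frequency | power above 25 Hz > ratio of total | 0.5 | muscle and electrical noise |
| low-frequency | power below 0.5 Hz > ratio of total | 0.9 | sweating/respiration/electrode drift |

The band components are obtained by zero-phase filtering of the whole
signal (4th-order responses: a 25 Hz high-pass and a 0.5 Hz low-pass) rather
than per-segment periodograms, because a 2-s segment has only 0.5 Hz
spectral resolution — far too coarse for a 0.2–0.5 Hz band. The order-4
low-pass matters: its passband is flat enough (≥ 99% amplitude at 0.25 Hz)
that a genuine slow drift can actually reach the 0.9 ratio, which a
2nd-order response (94% at 0.25 Hz, capping the ratio near 0.88) never
would. A flagged segment invalidates one neighbouring segment on each side
(guard band), since artifact onsets do not respect segment boundaries.

Artifacts are *excluded*, never interpolated: interpolation would fabricate
exactly the amplitude structure rEEG measures. Masked windows become
missing values; an epoch with under 50% valid windows is missing entirely.
All thresholds are exposed as arguments — they are conventional values, not
calibrated constants.

### rEEG

Per non-overlapping 2-s window, `rEEG = max − min` (µV). The per-window
values feed all statistics; a companion running mean (centred, 5 windows =
10 s, shrinking at the edges) exists purely for trend display. The 10-s
span is a display choice: long enough to suppress window-to-window jitter,
short enough to keep the burst structure visible. Long-term trends use the
*mean* of valid window values per 2.5-min epoch; short-term medians use the
per-epoch values by default (`pool_windows = TRUE` pools the raw windows
instead — both conventions are defensible, and with 4 epochs a side the
median over epochs is the more conservative unit).

### ASI

The Activation Synchrony Index quantifies burst co-occurrence between two
signals against a time-shifted surrogate null. The concrete instantiation
(all constants in `asi_params()`):

1. amplitude envelope = RMS in 1-s bins (long enough to smooth carrier
   oscillation, short enough to resolve ~3-s bursts);
2. each envelope quantized into 4 levels at its own quartiles — this makes
   the index exactly invariant to amplitude rescaling of either channel, so
   asymmetric electrode gains cannot fake synchrony;
3. `I0` = plug-in (joint-histogram) mutual information at zero lag, in bits;
4. null: 100 surrogates, each the MI after a circular shift of one envelope
   by a uniform draw from `[30 s, T − 30 s]` — shifting preserves each
   channel's full burst statistics while destroying alignment;
5. `ASI = log2(I0 / median surrogate MI)`, both floored at 1e-6 bits.

The ratio-of-MI form cancels the plug-in estimator's positive bias, which
is common to numerator and null; the median (not mean) of the surrogates
resists occasional near-alignments; the floor prevents `log` blow-up on
near-zero MI. Under independence the zero-lag MI is exchangeable with the
surrogates, so ASI ≈ 0 by construction and exceeds its own 95th-percentile
surrogate threshold ~5% of the time — the calibration the test suite
verifies (measured exceedance 0.02–0.08 over 200 runs). For identical
inputs the quartile quantization gives exactly uniform marginals, so
`I0 = log2(4) = 2` bits, the self-information bound. With 150–600 envelope
bins per segment the index is noisy (SD near 1 under independence at 600
bins); it is a *relative* measure, meaningful in trends and contrasts, not
an absolute synchrony scale.

### Short- and long-term designs

Short-term: baseline `[drug − 13 min, drug − 1 min)` (12 min), post
`[drug + 1 min, drug + 11 min)` (10 min), 1-min gaps absorbing timestamp
uncertainty; each window cut into 2.5-min epochs. 12 min / 2.5 min = 4.8,
so the floor rule keeps 4 complete epochs; they are anchored at the window
start by default, which drops the 120 s nearest the gap on the baseline
side (`anchor = "end"` keeps them instead — the choice is exposed because
no convention is canonical). The per-subject result is
`delta = median(post epochs) − median(baseline epochs)`, with a side
missing whenever it has no valid epoch. The baseline length is plain
configuration: the pipeline does not adapt it to data quality. Long-term:
consecutive 2.5-min epochs across the whole recording, per-subject trends
aligned on `drug_time` and averaged over subjects with data.

### Cohort statistics

All tests are nonparametric and two-sided: Spearman (average ranks; exact
permutation p for small untied samples, asymptotic otherwise), Wilcoxon
rank sum (exact for small untied groups, normal approximation with tie
correction otherwise), Kruskal–Wallis (tie-corrected H, χ² p on k−1 df).
The comparison plan is fixed *before* testing — rEEG on P3−P4, F3−F4 and
the four referential channels; ASI on the interhemispheric (F3−P3 vs
F4−P4), two intrahemispheric and the frontal pairings — and no
multiple-testing correction is applied, matching the a-priori-minimization
strategy; the family size is recorded in the output so users can correct if
they prefer. Missing subjects are dropped listwise; comparisons with fewer
than 5 subjects are reported as not-computed rather than silently skipped.

A caveat inherent to delta-versus-baseline designs: because measurement
noise in the baseline median enters the delta with opposite sign,
regression to the mean biases the null correlation slightly negative (mean
null rho ≈ −0.09 in our simulations, giving a ~7% false-positive rate at
α = 0.05 instead of the nominal 5%). This is a property of the design, not
of the implementation; interpretation of borderline negative correlations
should keep it in mind.

## The synthetic cohort

The generator produces what the features assume: discontinuous
neonatal-like EEG — alternating high-amplitude bursts (spontaneous activity
transients) and low-amplitude interburst intervals.

- **Burst timing**: renewal process; the gap between burst onsets is burst
  duration + interburst interval, with lognormal IBI (σ = 0.5 log-units,
  strictly positive and right-skewed) and lognormal durations (σ = 0.3).
  Defaults: 3-s bursts, 7-s IBI, hence 6 bursts/min — a plausible
  discontinuous tracing; the constructor rejects a `burst_rate` that
  disagrees with the durations by more than 20%.
- **Burst waveform**: 0.5–20 Hz band-limited noise under a half-sine
  envelope, each burst rescaled so its peak-to-peak equals the target
  amplitude; the interburst background is the same carrier at < 15% of the
  burst amplitude (~9% peak-to-peak). Subject amplitudes span 25–150 µV by
  default.
- **Synchrony**: each left-hemisphere burst is shared by the right with
  probability `sync_level` (onset jitter ≤ 0.2 s); unshared bursts are
  replaced from an independent train so both hemispheres keep the same
  burst rate. Within a hemisphere, frontal and parietal channels share
  bursts with probability 0.9 — coupled but imperfect, as intrahemispheric
  comparisons require. Carrier noise is independent per channel, so
  synchrony lives in burst timing (what ASI measures), not in waveforms.
- **Drug effect**: an instantaneous step at the timestamp — the analysis is
  a pre/post contrast, not pharmacokinetics. Burst amplitude (and the
  background with it) and interhemispheric sharing are multiplied by
  `max(0, 1 − slope × normalized_baseline)`, with `normalized_baseline` the
  subject's amplitude over the cohort maximum, keeping the multiplier in
  [0, 1]. With a common positive slope, higher-baseline subjects are
  suppressed more *by construction*, which is the effect the delta-vs-
  baseline correlation must recover. Note the multiplier is driven by the
  amplitude baseline; the ASI delta therefore correlates with the ASI
  baseline only through the sharing reduction, a deliberately weaker
  coupling.
- **Artifacts**: three injectable classes matched to the three detectors —
  ±1200 µV square excursions, sustained 100 µV 30 Hz oscillation, 300 µV
  0.25 Hz drift.

What the generator does **not** emulate: realistic spectra, sleep-state
cycling, maturational change, asymmetric pathology, ECG/pulse artifacts, or
any pharmacokinetic ramp. Passing the synthetic validation therefore shows
that the pipeline measures what it claims on signals with the assumed
burst-interburst structure; it does not certify performance on real
recordings, where burst morphology and artifact mixtures are richer.

## Validation scales

The test suite and `scripts/acceptance.R` run everything from scratch at
sizes chosen to finish on a single CPU while keeping the statistics
meaningful: cohort-level simulations (21 subjects, 50 cohorts per
condition) use recordings spanning 14 min before / 13 min after the drug —
just beyond the −13…+11 min the short-term design consumes — sampled at
100 Hz, which is still > 2× the 35 Hz band edge so every feature is
unchanged (all definitions are in seconds, not samples). Feature-level
checks (ASI calibration and synchrony grid, artifact detection, EDF round
trips) run at the full 250 Hz on 5–20 min recordings. The study-scale
defaults — 21 subjects, 2-h epochs either side, 250 Hz — remain the
package defaults throughout.

## Known limitations

- EDF support is deliberately minimal: 16-bit EDF/EDF+, one annotation
  channel, identical physical range per signal — enough for the four-channel
  montage this pipeline targets, not a general biosignal reader.
- The ASI constants (envelope bin, 4 levels, 100 surrogates, 30-s minimum
  shift) are this package's definition of the index; other instantiations
  of burst-synchrony measures will differ in scale, though the surrogate
  normalization makes the near-zero-under-independence property portable.
- The artifact detectors are threshold rules; they are validated against
  injected artifacts of the same three classes, not against annotated
  clinical artifacts.
- With 4 epochs per side, per-subject medians are coarse; the delta design
  carries the regression-to-the-mean caveat discussed above.
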