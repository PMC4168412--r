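---
title: "Pattern-matching ECG telemetry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-matching ECG telemetry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgpm)
```

## The problem

A wearable single-lead ECG transmitter that streams every raw sample costs
2 bytes per 10-bit sample — about 2.6 MB per hour at 360 Hz — almost all of
it describing beats that look exactly like the previous one. `ecgpm`
implements the alternative: learn the wearer's normal beat morphology once,
then transmit a 4-byte summary per normal beat and full waveform data only
for beats that deviate from the learned pattern. The receiver replays the
stored template for normal beats and splices in the transmitted waveforms
for abnormal ones, so the clinically interesting morphology always crosses
the link losslessly.

## The detection chain

R-peaks are found by a four-stage chain (`detect_rpeaks()`):

1. **35 Hz low-pass** — a 4th-order Butterworth applied forward–backward
   (zero phase), removing EMG and other high-frequency noise without
   shifting the R apex. We pad the signal by odd extension (half a second,
   mirrored and negated about each end point) before filtering so the
   filter's start-up transient falls entirely in the padding; without it a
   cold-started IIR filter produces an artificial edge swing large enough
   to be mistaken for a beat.
2. **Moving average** — a causal boxcar of `round(fs/60)` samples, which
   places a spectral null exactly on 60 Hz mains (use `round(fs/50)` in
   50 Hz regions).
3. **First difference, squared** — emphasises the steep QRS slopes over
   the smooth P and T waves.
4. **Adaptive threshold** — a candidate is a local maximum of the squared
   derivative exceeding `thr_fraction` times the running maximum over the
   trailing 2 s. Candidates closer than the 200 ms refractory period keep
   only the larger. Each accepted candidate is then refined to the maximum
   of the *low-pass* output within ±50 ms, so RR intervals are measured
   between true R apices. Refinement deliberately uses the stage-1 output
   rather than the stage-2 output: the causal boxcar delays its peak by
   `(width−1)/2` samples, which would bias every fiducial point.

**Why `thr_fraction = 0.1`.** The threshold must sit below the weakest
beat the detector is required to catch. A ventricular ectopic beat with a
QRS about three times wider than normal has roughly a three-fold lower
peak slope, hence close to one tenth of a normal beat's squared
derivative. T waves and in-band noise sit below 1 % of it, so 0.1 catches
wide beats with margin while staying an order of magnitude above
everything that is not a QRS. A fraction as high as 0.5 — natural if one
thinks on the amplitude rather than the squared scale — silently discards
exactly the beats the system exists to transmit.

Two guards keep the detector honest on degenerate input: candidates
within 100 ms of either record edge are ignored (no complete PQRST window
fits there, and residual filter edge effects live there), and candidates
below a machine-precision floor are ignored so that a perfectly flat
record yields zero beats rather than numerical dust.

## Windowing, quantization and the pattern matrix

Each beat is the window from 220 ms before to 380 ms after the R-peak:
`ceiling(0.220·fs) + 1 + ceiling(0.380·fs)` samples, i.e. 80 + 1 + 137 =
218 at 360 Hz. The window is quantized per beat to `A = 81` amplitude
levels by min–max scaling: level `round((x−min)/(max−min)·(A−1))`, a
constant window mapping to the middle level. Per-beat scaling makes the
matcher insensitive to slow gain and baseline drift between beats; the
amplitude *shape* is what is compared. (A 5-bit quantizer would give 32
levels; 81 is the resolution the matrix is specified at, and `A` is
configurable for anyone wanting the coarser grid.)

Training (`train_matrix()`) accumulates the quantized trajectories of the
beats from the first 30 s into an `n_total × A` occupancy matrix. For
every beat and time column, the cell at the beat's level *and its two
vertical neighbours* are each incremented, saturating at 10:

```
if PM[i, level]   < 10 then PM[i, level]   += 1
if PM[i, level−1] < 10 then PM[i, level−1] += 1
if PM[i, level+1] < 10 then PM[i, level+1] += 1
```

The ±1 smear is what gives the matcher its tolerance band. Thirty seconds
at a resting heart rate supplies ~35 beats, comfortably saturating the
trajectory cells.

**Matching.** A beat's `ratePM` is the number of time columns whose
quantized level lands on a cell with occupancy above 7 (≥ 8 training
hits). Matching tests only the exact cell — the tolerance band already
lives in the training smear, and testing ±1 at match time would double
it. A perfect self-match against a saturated matrix scores the full 218.
Beats with `ratePM > 180` are classified normal; at or below 180,
abnormal (the boundary case is deliberately abnormal: when in doubt,
transmit the waveform). An alternative screening threshold of 35 is kept
as the evaluation preset for retrospective database runs, where only
grossly deviant morphology should be flagged.

**Which signal is matched.** Patterns are extracted from the
noise-suppressed signal (stages 1–2 of the detection chain), not the raw
samples. The low-pass stage exists to remove noise that would otherwise
randomise the quantized levels: at 20 dB wideband SNR, raw-window levels
jitter by several quantization steps and normal beats lose 15 % or more
of their columns, which no fixed threshold can separate cleanly. The
*transmitted* waveforms and the reconstruction template remain raw ADC
samples — filtering is a matching aid, not a lossy step on the wire.

## The packet stream

The wire format is little-endian and self-framing:

| kind | layout | size |
|------|--------|------|
| `T` (template, first packet) | `0x54, fs:u16, len:u16, samples:u16×len` | 5 + 2·len |
| `N` (normal beat) | `0x4E, preRR:u16, ratePM:u8` | 4 |
| `A` (abnormal beat) | `0x41, preRR:u16, ratePM:u8, len:u16, samples:u16×len` | 6 + 2·len |

`preRR` is the RR interval in milliseconds (u16 covers 65.5 s); samples
are 10-bit ADC counts in 16-bit slots. Millivolt records are affinely
mapped onto 0–1023 before encoding, with the mapping kept alongside the
stream object on the transmitter/analysis side. At 218-sample windows,
swapping one normal beat for an abnormal one costs exactly 438 extra
bytes. No checksum is added; link integrity is the transport's job.

## Reconstruction

The receiver lays each beat's window — template for `N`, payload for `A`
— on a common time base, the first beat's R at the anchor position and
each later beat at the previous R plus its decoded preRR. Gaps between
windows are filled by linear interpolation between the adjacent window
edges: it adds no invented morphology and keeps the trace continuous.
When a premature beat's window overlaps its predecessor, the later window
overwrites from its first sample — the newly transmitted (by construction
more interesting) beat wins. Abnormal waveforms therefore survive the
whole encode → decode → reconstruct path bit-exactly in ADC units.

## Evaluation metrics

* **Compression ratio** — conventional cost (2 bytes × samples in the
  transmitted span) divided by actual stream bytes, reported as an exact
  quotient.
* **CC / RMSE** — both signals are min–max normalised to [0, 1] over the
  compared span before Pearson correlation and root-mean-square error, so
  RMSE is a fraction of the full amplitude range and unit-free.
* **R-peak accuracy** — greedy one-to-one matching of detected to
  reference peaks within ±50 ms; matched over reference, as a percentage.
* **Abnormal accuracy** — true positives over reference-abnormal count.
  Over-detection cannot inflate it past 100 %; false alarms
  (reference-normal beats classified abnormal) are reported separately.

## The synthetic generator

`synth_ecg()` emulates what the pipeline needs to be tested against, and
nothing more: quasi-periodic beats built from five Gaussian bumps
(P, Q, R, S, T at fixed offsets from the R apex), Gaussian RR variability
(default 30 ms sd around 72 bpm), a PVC-like abnormal class (no P wave,
3× wider and 1.3× taller R, inverted T, preceding RR × 0.7, default rate
5 %), and additive noise: sinusoidal baseline wander (default 0.05 mV at
0.25 Hz), sinusoidal mains (0.02 mV at 60 Hz) and white noise at a stated
SNR relative to the clean signal's variance (default 20 dB). The output
is quantized to a 10-bit ADC over a fixed −1.5 to 2.5 mV range, and
ground-truth R positions and labels ride along as annotations. Everything
is reproducible bit-for-bit from the seed.

The bump amplitudes and widths are fixtures chosen to look like a
plausible lead-II morphology; they are not fitted to any recording. What
the generator does *not* emulate: beat-to-beat morphology variability of
real hearts, respiration-modulated baseline, motion artifacts, electrode
pops, or the long-tailed RR dynamics of real arrhythmia. Tests passing on
this generator therefore demonstrate the pipeline's mechanics — detection
geometry, matrix arithmetic, codec exactness, threshold behaviour — not
clinical performance; retrospective database runs through the WFDB reader
and the evaluation preset are the route to the latter.

## Problem sizes and conventions

The test suite and acceptance script run entirely on generated data: the
invariant checks use 60 s records across 20 seeds, and the
parameter-recovery surface uses ten 420 s streams (~500 beats each, 5 %
abnormal, 20 dB SNR) — small enough to run in seconds, large enough that
a 95 % sensitivity/specificity bound is meaningful. Sample indices are
1-based throughout, as everywhere in R; quantized amplitude levels are
0-based values `0..A−1`, since they are levels rather than indices. The
codec, matrix arithmetic and generator are deterministic given a seed;
`which.max` tie-breaking (first maximum) fixes the refinement of flat-top
peaks.

## Known limitations

* One template per run: the matrix is never re-trained, so gradual
  morphology drift (posture, electrode movement) degrades specificity
  over long recordings. Periodic re-training is the natural extension.
* A beat-level binary classifier: no per-arrhythmia typing, and rhythm
  labels (`classify_rhythm()`) are a plain rate banding.
* The adaptive-threshold detector has no search-back, so a beat weaker
  than `thr_fraction` of a recent large artifact can be missed.
* The reconstruction of normal beats is the template by definition;
  subtle within-normal variation is not preserved — that is the point of
  the compression, but it makes the CC/RMSE figures a property of the
  wearer's morphological stability as much as of the codec.
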