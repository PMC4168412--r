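# ecgpm — pattern-matching packet generation for wearable ECG telemetry

`ecgpm` is an R implementation of a low-bandwidth ECG telemetry
transmitter/receiver pair for single-lead wearable monitors, plus the
tooling to evaluate it. Streaming raw ECG costs 2 bytes per 10-bit sample;
almost all of that traffic describes heartbeats that look exactly like the
previous one. The idea here is to learn the wearer's normal beat morphology
during a short training span and then send full waveform data **only for
beats that deviate from it** — a 4-byte message suffices for everything
else — while the receiver reconstructs a continuous trace from the stored
template and the transmitted abnormal waveforms.

## The method

* **R-peak detection.** 35 Hz zero-phase Butterworth low-pass → causal
  boxcar of `fs/60` samples (spectral null on 60 Hz mains) → first
  difference, squared → adaptive threshold: a candidate local maximum must
  exceed a fraction of the running maximum of the squared derivative over
  the trailing 2 s, with a 200 ms refractory period. Accepted candidates
  are refined to the R apex on the filtered signal within ±50 ms.

* **Pattern matrix.** Each beat is the window `[R − 220 ms, R + 380 ms]`
  (218 samples at 360 Hz), min–max quantized to `A = 81` amplitude levels.
  Training accumulates an `n × A` occupancy matrix `PM` over ~30 s of
  beats; for each time column `i` with beat level `ℓᵢ`, the cells
  `PM[i, ℓᵢ−1], PM[i, ℓᵢ], PM[i, ℓᵢ+1]` are incremented, saturating at 10.

* **Classification.** For an incoming beat,
  `ratePM = #{ i : PM[i, ℓᵢ] > 7 }` counts time columns landing on
  well-supported cells (max 218). `ratePM > 180` ⇒ normal (`N`),
  otherwise abnormal (`A`).

* **Packets.** One leading template packet `T` (fs + mean training
  window), then per beat: `N` = `[0x4E, preRR:u16, ratePM:u8]` (4 bytes)
  or `A` = `[0x41, preRR:u16, ratePM:u8, len:u16, waveform:u16×len]`
  (442 bytes at 218 samples). Little-endian, self-framing, bit-exact
  round trip.

* **Reconstruction & metrics.** Template playback for `N`, transmitted
  waveform for `A`, R-peaks placed by accumulated preRR, linear
  interpolation across gaps; evaluated by compression ratio
  (`CR = raw bytes / transmitted bytes`), Pearson CC and RMSE on min–max
  normalised signals, and R-peak / abnormal detection accuracy.

A seeded synthetic ECG generator (Gaussian-bump PQRST beats, PVC-like
abnormal class, baseline/mains/white noise, ground-truth annotations)
makes the whole pipeline testable without external recordings; a minimal
WFDB reader (formats 16 and 212 + MIT annotations) supports retrospective
database runs.

## Worked example

```r
library(ecgpm)

rec <- synth_ecg(synth_config(duration_s = 180, seed = 42))
rec
#> <ecg_record> 64800 samples @ 360 Hz (180.0 s), units=adc
#>   220 annotated beats (14 abnormal)

res <- run_pipeline(rec, train_seconds = 30)
res$report
#> <eval_report>
#>   compression ratio : 21.07 (107774 raw / 5115 tx bytes)
#>   correlation (CC)  : 0.943
#>   RMSE (0-1 scale)  : 0.035
#>   R-peak accuracy   : 100.0%
#>   abnormal accuracy : 100.0% (9/9, 0 false alarms)
```

Reading the report: the first 30 s trained the pattern matrix; the
remaining 150 s were transmitted in 5,115 bytes instead of the 107,774 a
conventional streamer would need (CR 21.1:1). Every reference R-peak in
the transmitted span was detected within ±50 ms, and all 9 reference
abnormal beats there were classified abnormal with no false alarm, so
their waveforms crossed the link bit-exactly. The reconstructed trace
correlates 0.943 with the original at an RMSE of 3.5 % of the amplitude
range — the residual is normal-beat variability replaced by the template,
which is precisely what the codec discards.

The same flow is scriptable from a shell via the thin CLI at
`inst/cli/ecgpm` (subcommands `simulate`, `detect`, `train`, `encode`,
`decode`, `reconstruct`, `evaluate`, `pipeline`).

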