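#' Synthetic ECG configuration
#'
#' Study conditions for the seeded single-lead ECG simulator. Each beat
#' is a sum of five Gaussian bumps (P, Q, R, S, T) at fixed offsets from
#' the R apex; RR intervals vary normally around the mean heart rate. A
#' minority class of PVC-like abnormal beats has no P wave, a wide
#' (x3) and taller (x1.3) R bump, an inverted T wave, and premature
#' timing (preceding RR multiplied by `abnormal_prematurity`). Additive
#' noise comprises sinusoidal baseline wander, sinusoidal mains
#' interference, and white noise at a stated SNR relative to the clean
#' signal's variance. The result is quantized to a 10-bit ADC range.
#'
#' @param fs sampling rate, Hz.
#' @param duration_s record length, s.
#' @param mean_hr_bpm mean heart rate, beats/min.
#' @param rr_sd_ms RR-interval standard deviation, ms.
#' @param abnormal_rate per-beat probability of an abnormal beat.
#' @param abnormal_prematurity RR multiplier for the interval preceding
#'   an abnormal beat (< 1 means premature).
#' @param white_snr_db white-noise SNR in dB relative to the clean
#'   signal's variance; `Inf` disables it.
#' @param baseline_amp_mv,baseline_hz baseline-wander sine amplitude (mV)
#'   and frequency (Hz).
#' @param mains_amp_mv,mains_hz powerline sine amplitude (mV) and
#'   frequency (Hz); `fs` must exceed twice `mains_hz`.
#' @param adc_range_mv two-element mV range mapped onto ADC counts
#'   0--1023.
#' @param seed integer RNG seed; identical seed + config reproduce the
#'   record bit for bit.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(fs = 360, duration_s = 60, mean_hr_bpm = 72,
                         rr_sd_ms = 30, abnormal_rate = 0.05,
                         abnormal_prematurity = 0.7,
                         white_snr_db = 20, baseline_amp_mv = 0.05,
                         baseline_hz = 0.25, mains_amp_mv = 0.02,
                         mains_hz = 60, adc_range_mv = c(-1.5, 2.5),
                         seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, mean_hr_bpm > 0, rr_sd_ms >= 0,
            abnormal_rate >= 0, abnormal_rate <= 1,
            abnormal_prematurity > 0,
            length(adc_range_mv) == 2L, diff(adc_range_mv) > 0)
  if (mains_amp_mv > 0 && fs <= 2 * mains_hz) {
    stop("fs must exceed twice the mains frequency", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

# fixed morphology of one beat: Gaussian bumps, offsets in seconds
# relative to the R apex, amplitudes in mV, widths as Gaussian sd (s)
synth_bumps <- function(abnormal = FALSE) {
  b <- data.frame(
    wave  = c("P", "Q", "R", "S", "T"),
    mu    = c(-0.170, -0.025, 0.000, 0.028, 0.230),
    amp   = c(0.15, -0.12, 1.20, -0.25, 0.35),
    sigma = c(0.025, 0.010, 0.012, 0.010, 0.055)
  )
  if (abnormal) {
    b$amp[b$wave == "P"] <- 0
    b$amp[b$wave == "R"] <- b$amp[b$wave == "R"] * 1.3
    b$sigma[b$wave == "R"] <- b$sigma[b$wave == "R"] * 3
    b$amp[b$wave == "T"] <- -b$amp[b$wave == "T"]
  }
  b
}

#' Generate a synthetic annotated ECG record
#'
#' See [synth_config()] for the signal model. Ground-truth annotations
#' (R-peak sample index and normal/abnormal label) are attached to the
#' returned record, which makes every downstream stage testable without
#' external recordings.
#'
#' @param config a [synth_config()].
#' @return an [ecg_record] with `units = "adc"` and ground-truth
#'   annotations; the generating config is attached as attribute
#'   `"config"`.
#' @export
synth_ecg <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  rr_mean <- 60 / config$mean_hr_bpm
  rr_sd <- config$rr_sd_ms / 1000

  # beat schedule: first R at 0.8 s, stop 0.6 s before the end so every
  # beat's full PQRST support stays inside the record
  t_beats <- numeric(0); abnormal <- logical(0)
  t_cur <- 0.8
  repeat {
    ab <- stats::runif(1) < config$abnormal_rate
    if (length(t_beats) > 0L) {
      rr <- max(0.3, stats::rnorm(1, rr_mean, rr_sd))
      if (ab) rr <- rr * config$abnormal_prematurity
      t_cur <- t_cur + rr
    }
    if (t_cur > config$duration_s - 0.6) break
    t_beats <- c(t_beats, t_cur)
    abnormal <- c(abnormal, ab)
  }
  if (length(t_beats) == 0L) {
    stop("duration too short to place any beat", call. = FALSE)
  }

  tt <- (seq_len(n) - 1L) / fs
  clean <- numeric(n)
  bump_n <- synth_bumps(FALSE)
  bump_a <- synth_bumps(TRUE)
  for (k in seq_along(t_beats)) {
    b <- if (abnormal[k]) bump_a else bump_n
    lo_t <- t_beats[k] - 0.45; hi_t <- t_beats[k] + 0.55
    i <- max(1L, as.integer(floor(lo_t * fs)) + 1L):min(n, as.integer(ceiling(hi_t * fs)) + 1L)
    dt <- tt[i] - t_beats[k]
    for (j in seq_len(nrow(b))) {
      if (b$amp[j] != 0) {
        clean[i] <- clean[i] + b$amp[j] * exp(-(dt - b$mu[j])^2 / (2 * b$sigma[j]^2))
      }
    }
  }

  x <- clean
  if (config$baseline_amp_mv > 0) {
    x <- x + config$baseline_amp_mv *
      sin(2 * pi * config$baseline_hz * tt + stats::runif(1, 0, 2 * pi))
  }
  if (config$mains_amp_mv > 0) {
    x <- x + config$mains_amp_mv *
      sin(2 * pi * config$mains_hz * tt + stats::runif(1, 0, 2 * pi))
  }
  if (is.finite(config$white_snr_db)) {
    noise_sd <- sqrt(stats::var(clean) / 10^(config$white_snr_db / 10))
    x <- x + stats::rnorm(n, 0, noise_sd)
  }

  lo <- config$adc_range_mv[1L]; hi <- config$adc_range_mv[2L]
  adc <- pmin(1023L, pmax(0L, as.integer(round((x - lo) / (hi - lo) * 1023))))

  ann <- data.frame(
    sample_index = as.integer(round(t_beats * fs)) + 1L,
    label = ifelse(abnormal, "abnormal", "normal"),
    stringsAsFactors = FALSE
  )
  rec <- ecg_record(adc, fs = fs, units = "adc", annotations = ann)
  attr(rec, "config") <- config
  rec
}
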