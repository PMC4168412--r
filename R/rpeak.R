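#' R-peak detector parameters
#'
#' Parameters of the detection chain: 35 Hz low-pass filter, moving-average
#' mains suppression, first derivative, and an adaptive threshold on the
#' squared derivative.
#'
#' @param fs sampling rate in Hz (used for the default boxcar width).
#' @param lp_cutoff low-pass corner frequency in Hz; 35 Hz keeps the QRS
#'   energy while rejecting EMG/high-frequency noise.
#' @param ma_width boxcar width in samples; the default `round(fs/60)`
#'   places a spectral null exactly on 60 Hz mains (use `round(fs/50)` in
#'   50 Hz regions).
#' @param refractory_ms minimum physiological spacing between accepted
#'   peaks, ms.
#' @param thr_fraction candidate threshold as a fraction of the trailing
#'   running maximum of the squared derivative, in (0, 1). The default
#'   0.1 is set by the widest beats the detector must catch: a
#'   ventricular beat with a 3x wider QRS has roughly a 3x lower peak
#'   slope, i.e. about 1/9 of a normal beat's squared derivative, while
#'   T waves and in-band noise stay below 1% of it.
#' @param thr_window_s length of the trailing window for the running
#'   maximum, seconds.
#' @return a list of class `rpeak_params`.
#' @export
rpeak_params <- function(fs, lp_cutoff = 35, ma_width = max(1L, round(fs / 60)),
                         refractory_ms = 200, thr_fraction = 0.1,
                         thr_window_s = 2) {
  stopifnot(lp_cutoff > 0, ma_width >= 1, refractory_ms > 0,
            thr_fraction > 0, thr_fraction < 1, thr_window_s > 0)
  structure(list(lp_cutoff = lp_cutoff, ma_width = as.integer(ma_width),
                 refractory_ms = refractory_ms, thr_fraction = thr_fraction,
                 thr_window_s = thr_window_s),
            class = "rpeak_params")
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt]), so the passband is flat (DC gain 1) and R-peak
#' positions are not shifted by group delay.
#'
#' @param record an [ecg_record].
#' @param cutoff corner frequency in Hz, strictly below Nyquist.
#' @return an [ecg_record] with filtered samples (same length and fs).
#' @export
lowpass_filter <- function(record, cutoff = 35) {
  stopifnot(inherits(record, "ecg_record"))
  if (cutoff >= record$fs / 2) {
    stop("low-pass cutoff must be below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  bf <- signal::butter(4, cutoff / (record$fs / 2), type = "low")
  x <- record$samples
  n <- length(x)
  # odd-extension padding confines the filter's start-up transient to the
  # padding, so the retained span sees the true zero-phase response
  pad <- min(n - 1L, max(15L, as.integer(round(record$fs / 2))))
  if (pad > 0L) {
    xe <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- signal::filtfilt(bf, xe)[(pad + 1L):(pad + n)]
  } else {
    y <- signal::filtfilt(bf, x)
  }
  new_ecg_record(y, record$fs, record$units, record$annotations)
}

#' Causal moving-average filter
#'
#' Boxcar mean of the trailing `width` samples; at the signal start the
#' available prefix is averaged. A `width`-sample boxcar has spectral
#' nulls at multiples of `fs/width`, which is how mains interference is
#' suppressed (width `fs/60` nulls 60 Hz).
#'
#' @param record an [ecg_record].
#' @param width window width in samples, >= 1.
#' @return an [ecg_record], same length.
#' @export
moving_average <- function(record, width) {
  stopifnot(inherits(record, "ecg_record"))
  width <- as.integer(width)
  if (width < 1L) stop("moving-average width must be >= 1", call. = FALSE)
  x <- record$samples
  n <- length(x)
  if (width > n) stop("moving-average width exceeds signal length", call. = FALSE)
  cs <- cumsum(x)
  y <- numeric(n)
  head_n <- seq_len(min(width, n))
  y[head_n] <- cs[head_n] / head_n
  if (n > width) {
    i <- (width + 1L):n
    y[i] <- (cs[i] - cs[i - width]) / width
  }
  new_ecg_record(y, record$fs, record$units, record$annotations)
}

#' First difference of a signal
#'
#' `y[n] = x[n] - x[n-1]` with `y[1] = 0`; emphasises the steep QRS slopes
#' over the smoother P and T waves.
#'
#' @param record an [ecg_record] (length >= 2).
#' @return numeric vector, same length as the input.
#' @export
first_derivative <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  if (length(x) < 2L) stop("need at least 2 samples to differentiate", call. = FALSE)
  c(0, diff(x))
}

#' Detect R-peaks with an adaptive threshold
#'
#' Runs the full chain: low-pass filter, moving average, first derivative,
#' squaring. A candidate is a local maximum of the squared derivative that
#' exceeds `thr_fraction` times the running maximum over the trailing
#' `thr_window_s` seconds. Candidates closer than the refractory period
#' keep only the larger one. Each accepted candidate is then refined to the
#' absolute maximum of the low-pass-filtered ECG within +/-50 ms, so peak
#' positions (and hence RR intervals) refer to the R apex rather than the
#' maximal slope.
#'
#' @param record an [ecg_record], at least `thr_window_s` seconds long.
#' @param params an [rpeak_params] object.
#' @return list of class `rpeak_result` with `peaks` (ascending 1-based
#'   sample indices) and `preRR_ms` (RR interval preceding each peak in
#'   ms; `NA` for the first peak).
#' @export
detect_rpeaks <- function(record, params = rpeak_params(record$fs)) {
  stopifnot(inherits(record, "ecg_record"), inherits(params, "rpeak_params"))
  fs <- record$fs
  n <- length(record$samples)
  if (n < params$thr_window_s * fs) {
    stop("record shorter than the threshold window", call. = FALSE)
  }
  lp <- lowpass_filter(record, params$lp_cutoff)
  ma <- moving_average(lp, params$ma_width)
  d2 <- first_derivative(ma)^2

  w <- max(2L, as.integer(round(params$thr_window_s * fs)))
  thr <- params$thr_fraction * rolling_max_trailing(d2, w)
  cand <- local_maxima(d2)
  # numerical floor: filtering a constant signal leaves double-rounding
  # dust; anything at machine-precision scale is not a beat
  floor_d2 <- (sqrt(.Machine$double.eps) * max(1e-12, max(abs(ma$samples))))^2
  cand <- cand[d2[cand] > thr[cand] & d2[cand] > floor_d2]
  # zero-phase filtering leaves edge transients; drop candidates in the
  # first/last 100 ms (no complete PQRST window fits there anyway)
  margin <- as.integer(round(0.1 * fs))
  cand <- cand[cand > margin & cand <= n - margin]

  refr <- as.integer(round(params$refractory_ms / 1000 * fs))
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0L || i - keep[length(keep)] >= refr) {
      keep <- c(keep, i)
    } else if (d2[i] > d2[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }

  # refine to the R apex on the zero-phase filtered ECG
  half <- as.integer(round(0.050 * fs))
  lp_x <- lp$samples
  peaks <- vapply(keep, function(i) {
    a <- max(1L, i - half); b <- min(n, i + half)
    a + which.max(lp_x[a:b]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))

  # refinement can move two candidates inside the refractory span: keep
  # the taller apex
  if (length(peaks) > 1L) {
    out <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- out[length(out)]
      if (p - last >= refr) {
        out <- c(out, p)
      } else if (lp_x[p] > lp_x[last]) {
        out[length(out)] <- p
      }
    }
    peaks <- out
  }

  pre_rr <- c(NA_real_, diff(peaks) * 1000 / fs)
  structure(list(peaks = peaks, preRR_ms = pre_rr, fs = fs),
            class = "rpeak_result")
}

#' @export
print.rpeak_result <- function(x, ...) {
  cat(sprintf("<rpeak_result> %d peaks", length(x$peaks)))
  if (length(x$peaks) > 1L) {
    cat(sprintf(", median RR %.0f ms", stats::median(x$preRR_ms, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Rate-based rhythm label from an RR interval
#'
#' Classifies each RR interval by instantaneous heart rate
#' (`HR = 60000/preRR`): above `tachy_bpm` is tachycardia, below
#' `brady_bpm` is bradycardia, otherwise a normal rate. The boundaries are
#' inclusive in the normal band (exactly 60 or 100 bpm is `normal_rate`).
#'
#' @param preRR_ms RR interval(s) in milliseconds, > 0.
#' @param brady_bpm,tachy_bpm rate bounds in beats per minute.
#' @return character vector in `{"bradycardia","normal_rate","tachycardia"}`.
#' @export
classify_rhythm <- function(preRR_ms, brady_bpm = 60, tachy_bpm = 100) {
  if (any(!is.finite(preRR_ms) | preRR_ms <= 0)) {
    stop("preRR must be positive and finite", call. = FALSE)
  }
  hr <- 60000 / preRR_ms
  ifelse(hr > tachy_bpm, "tachycardia",
         ifelse(hr < brady_bpm, "bradycardia", "normal_rate"))
}
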