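test_that("low-pass filter has unit DC gain and the expected band edges", {
  fs <- 360
  t <- seq(0, 4, by = 1 / fs)
  const <- ecg_record(rep(7, length(t)), fs, units = "mV")
  expect_equal(lowpass_filter(const, 35)$samples, rep(7, length(t)),
               tolerance = 1e-6)

  mid <- seq(fs, 3 * fs)  # avoid edge transients when measuring gain
  pass <- ecg_record(sin(2 * pi * 5 * t), fs, units = "mV")
  expect_gte(max(abs(lowpass_filter(pass, 35)$samples[mid])), 0.99)

  stopband <- ecg_record(sin(2 * pi * 120 * t), fs, units = "mV")
  expect_lte(max(abs(lowpass_filter(stopband, 35)$samples[mid])), 0.1)

  expect_error(lowpass_filter(pass, 200), "Nyquist")
})

test_that("moving average is identity at width 1 and nulls fs/width", {
  fs <- 360
  t <- seq(0, 2, by = 1 / fs)
  x <- ecg_record(rnorm(length(t)), fs, units = "mV")
  expect_equal(moving_average(x, 1)$samples, x$samples)

  const <- ecg_record(rep(5, length(t)), fs, units = "mV")
  expect_equal(moving_average(const, 4)$samples, rep(5, length(t)))

  mains <- ecg_record(sin(2 * pi * 60 * t), fs, units = "mV")
  y <- moving_average(mains, 6)$samples
  expect_lte(max(abs(y[-(1:6)])), 0.01)  # 6-sample boxcar null at 60 Hz

  expect_error(moving_average(x, 0), ">= 1")
})

test_that("first derivative is the lagged difference with a zero head", {
  fs <- 100
  expect_equal(first_derivative(ecg_record(rep(4, 10), fs, units = "mV")),
               rep(0, 10))
  ramp <- ecg_record(3 * (0:9), fs, units = "mV")
  expect_equal(first_derivative(ramp), c(0, rep(3, 9)))
  expect_equal(first_derivative(ecg_record(c(0, 1, 0), fs, units = "mV")),
               c(0, 1, -1))
  expect_error(first_derivative(ecg_record(1, fs, units = "mV")),
               "2 samples")
})

test_that("detector finds every noise-free beat at the exact R apex", {
  rec <- synth_ecg(noise_free_config(seed = 1))
  det <- detect_rpeaks(rec)
  truth <- rec$annotations$sample_index
  expect_equal(length(det$peaks), length(truth))
  expect_lte(max(abs(det$peaks - truth)), 1)
  # preRR invariant
  expect_true(is.na(det$preRR_ms[1]))
  expect_equal(det$preRR_ms[-1], diff(det$peaks) * 1000 / rec$fs)
})

test_that("detector reports nothing on a flat signal and rejects short input", {
  flat <- ecg_record(rep(512, 3600), 360)
  expect_length(detect_rpeaks(flat)$peaks, 0)
  expect_error(detect_rpeaks(ecg_record(rep(512, 100), 360)), "shorter")
})

test_that("detection matches >= 98% of beats under 20 dB white noise", {
  cfg <- synth_config(duration_s = 60, seed = 2, abnormal_rate = 0,
                      white_snr_db = 20, baseline_amp_mv = 0, mains_amp_mv = 0)
  rec <- synth_ecg(cfg)
  det <- detect_rpeaks(rec)
  acc <- rpeak_accuracy(det$peaks, rec$annotations$sample_index, rec$fs,
                        tol_ms = 50)
  expect_gte(acc, 98)
})

test_that("detection is deterministic and honours the refractory period", {
  cfg <- synth_config(duration_s = 45, seed = 7)
  rec <- synth_ecg(cfg)
  p <- rpeak_params(rec$fs)
  d1 <- detect_rpeaks(rec, p)
  d2 <- detect_rpeaks(rec, p)
  expect_identical(d1$peaks, d2$peaks)
  refr <- p$refractory_ms / 1000 * rec$fs
  expect_true(all(diff(d1$peaks) >= refr))
  expect_true(all(diff(d1$peaks) > 0))
})

test_that("noise-free sensitivity and precision are 100% across seeds", {
  for (s in 1:20) {
    rec <- synth_ecg(noise_free_config(seed = s, abnormal_rate = 0.05))
    det <- detect_rpeaks(rec)
    truth <- rec$annotations$sample_index
    tol <- 0.05 * rec$fs
    m <- sapply(truth, function(r) min(abs(det$peaks - r)) <= tol)
    fp <- sapply(det$peaks, function(p) min(abs(truth - p)) > tol)
    expect_true(all(m), label = sprintf("sensitivity, seed %d", s))
    expect_false(any(fp), label = sprintf("precision, seed %d", s))
  }
})

test_that("rhythm labels follow the heart-rate bands", {
  expect_equal(classify_rhythm(1000), "normal_rate")   # 60 bpm, inclusive
  expect_equal(classify_rhythm(600), "normal_rate")    # 100 bpm, inclusive
  expect_equal(classify_rhythm(500), "tachycardia")    # 120 bpm
  expect_equal(classify_rhythm(1500), "bradycardia")   # 40 bpm
  expect_equal(classify_rhythm(c(500, 1500, 800)),
               c("tachycardia", "bradycardia", "normal_rate"))
  expect_error(classify_rhythm(0), "positive")
})
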