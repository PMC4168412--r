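test_that("window geometry follows the 220/380 ms rule", {
  s360 <- window_spec(360)
  expect_equal(s360$n_pre, 80L)
  expect_equal(s360$n_post, 137L)
  expect_equal(s360$n_total, 218L)
  s250 <- window_spec(250)
  expect_equal(c(s250$n_pre, s250$n_post, s250$n_total), c(55L, 95L, 151L))
})

test_that("PQRST extraction returns the inclusive window or drops the beat", {
  rec <- ecg_record(seq_len(2000), 360, units = "mV")
  spec <- window_spec(360)
  w <- extract_pqrst(rec, 500, spec)
  expect_length(w, 218L)
  expect_equal(w, 420:637)               # r - 80 .. r + 137
  expect_warning(out <- extract_pqrst(rec, 50, spec), "dropped")
  expect_null(out)
  expect_warning(extract_pqrst(rec, 1950, spec), "dropped")
})

test_that("quantization maps min to 0, max to A-1, constants to the middle", {
  qb <- quantize_beat(c(0, 511.5, 1023), A = 81)
  expect_equal(qb$levels, c(0L, 40L, 80L))
  expect_equal(quantize_beat(rep(3.3, 218), A = 81)$levels, rep(40L, 218))
  w <- make_pqrst_window()
  q <- quantize_beat(w, A = 81)
  expect_equal(q$levels[which.min(w)], 0L)
  expect_equal(q$levels[which.max(w)], 80L)
  expect_true(all(q$levels >= 0L & q$levels <= 80L))
})

test_that("training smears one cell up and down and saturates at 10", {
  lv <- c(0L, 3L, 8L, 8L, 4L)
  A <- 9L
  m1 <- train_matrix(list(levels_to_beat(lv, A)), A = A)
  for (i in seq_along(lv)) {
    hit <- lv[i] + 1L + c(-1L, 0L, 1L)
    hit <- hit[hit >= 1L & hit <= A]
    expect_equal(sum(m1$cells[i, ]), length(hit))
    expect_true(all(m1$cells[i, hit] == 1L))
  }
  # 12 identical beats: trajectory saturates at the cap
  m12 <- train_matrix(rep(list(levels_to_beat(lv, A)), 12L), A = A)
  expect_equal(unname(m12$cells[cbind(seq_along(lv), lv + 1L)]),
               rep(10L, length(lv)))
  expect_lte(max(m12$cells), 10L)
})

test_that("vectorised training equals the brute-force cell rules", {
  for (s in 0:9) {
    set.seed(s)
    A <- 9L; n <- 20L
    lvs <- lapply(1:50, function(i) rand_levels(n, A))
    m <- train_matrix(lapply(lvs, levels_to_beat, A = A), A = A)
    bf <- brute_force_train(lvs, A)
    expect_identical(m$cells, bf)
    for (lv in lvs[1:5]) {
      expect_equal(compute_ratepm(m, levels_to_beat(lv, A)),
                   brute_force_ratepm(bf, lv))
    }
  }
})

test_that("ratePM is 218 on self-match, 0 against untrained or shifted cells", {
  w <- make_pqrst_window()
  qb <- quantize_beat(w, A = 81)
  m <- train_matrix(rep(list(qb), 10L), A = 81)
  expect_equal(compute_ratepm(m, qb), 218L)

  m0 <- train_matrix(list(levels_to_beat(rep(40L, 218), 81)), A = 81)
  m0$cells[] <- 0L
  expect_equal(compute_ratepm(m0, qb), 0L)

  # a +2 level shift escapes the +/-1 training smear everywhere
  set.seed(5)
  lv <- sample(0:78, 218, replace = TRUE)
  m2 <- train_matrix(rep(list(levels_to_beat(lv, 81)), 10L), A = 81)
  expect_equal(compute_ratepm(m2, levels_to_beat(lv + 2L, 81)), 0L)
  expect_equal(compute_ratepm(m2, levels_to_beat(lv, 81)), 218L)
})

test_that("beat classification threshold is strict and boundary-abnormal", {
  expect_equal(classify_beat(218, 180), "N")
  expect_equal(classify_beat(102, 180), "A")
  expect_equal(classify_beat(180, 180), "A")
  expect_equal(classify_beat(c(200, 150), 180), c("N", "A"))
})

test_that("training never decreases a cell and is order-independent below cap", {
  set.seed(11)
  A <- 9L; n <- 20L
  lvs <- lapply(1:6, function(i) rand_levels(n, A))  # few beats: no saturation
  beats <- lapply(lvs, levels_to_beat, A = A)
  m_all <- train_matrix(beats, A = A)
  m_perm <- train_matrix(beats[sample(length(beats))], A = A)
  expect_identical(m_all$cells, m_perm$cells)
  # monotonicity: adding a beat never lowers any cell or any ratePM
  m_less <- train_matrix(beats[-1], A = A)
  expect_true(all(m_all$cells >= m_less$cells))
  probe <- levels_to_beat(rand_levels(n, A), A)
  expect_gte(compute_ratepm(m_all, probe), compute_ratepm(m_less, probe))
})

test_that("train_from_record builds a matrix the training beats match", {
  rec <- synth_ecg(noise_free_config(seed = 3))
  m <- train_from_record(rec, train_seconds = 30)
  expect_gte(m$trained_beats, 30L)
  expect_equal(m$n_total, 218L)
  expect_length(m$template, 218L)
  # every training beat scores a near-perfect ratePM against the matrix
  p <- rpeak_params(rec$fs)
  sub <- ecg_record(rec$samples[1:(30 * rec$fs)], rec$fs)
  det <- detect_rpeaks(sub, p)
  filt <- moving_average(lowpass_filter(sub, 35), p$ma_width)
  for (pk in det$peaks) {
    w <- suppressWarnings(extract_pqrst(filt, pk))
    if (is.null(w)) next
    expect_gte(compute_ratepm(m, quantize_beat(w, 81)), 200L)
  }
  expect_error(train_from_record(synth_ecg(noise_free_config(seed = 1, duration_s = 41)),
                                 train_seconds = 60), "too short")
})

test_that("pattern matrix serialization round trips", {
  rec <- synth_ecg(noise_free_config(seed = 4, duration_s = 45))
  m <- train_from_record(rec, train_seconds = 30)
  p <- withr::local_tempfile(fileext = ".pmx")
  write_pattern_matrix(m, p)
  back <- read_pattern_matrix(p)
  expect_identical(back$cells, m$cells)
  expect_equal(back$trained_beats, m$trained_beats)
  expect_equal(back$template, m$template, tolerance = 1e-6)  # float32 storage
  expect_error(read_pattern_matrix(write_csv_signal(ecg_record(1:99, 1), p)),
               "magic")
})

test_that("training rejects degenerate input", {
  expect_error(train_matrix(list()), "at least one")
  b1 <- levels_to_beat(rand_levels(10, 9), 9)
  b2 <- levels_to_beat(rand_levels(12, 9), 9)
  expect_error(train_matrix(list(b1, b2)), "mixed")
})
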