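test_that("ecg_record enforces its invariants", {
  expect_error(ecg_record(numeric(0), 360), "non-empty")
  expect_error(ecg_record(c(1, 2), 0), "positive")
  expect_error(ecg_record(c(0, 2000), 360, units = "adc"), "1023")
  expect_silent(ecg_record(c(-3.2, 5.1), 360, units = "mV"))
  ann <- data.frame(sample_index = c(5, 2), label = c("abnormal", "normal"))
  rec <- ecg_record(1:10, 360, annotations = ann)
  expect_equal(rec$annotations$sample_index, c(2L, 5L))  # sorted
  expect_error(ecg_record(1:10, 360,
    annotations = data.frame(sample_index = 11, label = "normal")),
    "bounds")
})

test_that("CSV signal round trip is lossless", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1", "2", "3"), p)
  rec <- read_csv_signal(p, fs = 360)
  expect_equal(rec$samples, c(1, 2, 3))
  expect_equal(rec$fs, 360)

  rec2 <- ecg_record(c(0, 1023), fs = 250)
  write_csv_signal(rec2, p)
  expect_equal(readLines(p), c("0", "1023"))
  expect_equal(read_csv_signal(p, 250)$samples, c(0, 1023))

  # mV floats preserved to well beyond 6 significant digits
  mv <- ecg_record(c(-0.123456, 1.234567, 0.000012345), fs = 250, units = "mV")
  write_csv_signal(mv, p)
  back <- read_csv_signal(p, 250, units = "mV")
  expect_equal(back$samples, mv$samples, tolerance = 1e-9)
})

test_that("CSV reader rejects empty and non-numeric input with a location", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), p)
  expect_error(read_csv_signal(p, 360), "empty")
  writeLines(c("amplitude", "1", "oops", "3"), p)  # header is tolerated
  expect_error(read_csv_signal(p, 360), "line 2")
  writeLines(c("amplitude", "1", "2", "3"), p)
  expect_equal(read_csv_signal(p, 360)$samples, c(1, 2, 3))
})

test_that("annotation CSV round trip preserves indices and labels", {
  p <- withr::local_tempfile(fileext = ".csv")
  ann <- data.frame(sample_index = c(100L, 460L),
                    label = c("normal", "abnormal"))
  rec <- ecg_record(1:1000, 360, annotations = ann)
  write_csv_annotations(rec, p)
  expect_equal(read_csv_annotations(p), ann)
})

test_that("WFDB write-then-read round trips format 16 with annotations", {
  dir <- withr::local_tempdir()
  x <- as.integer(round(200 * sin(seq(0, 6 * pi, length.out = 720))))
  base <- write_wfdb_fixture(dir, "fix16", list(x), fs = 360,
                             ann = data.frame(time = c(100L, 460L),
                                              code = c(1L, 5L)))  # N, V
  rec <- read_wfdb_record(base, channel = 1)
  expect_equal(rec$fs, 360)
  expect_equal(rec$units, "mV")
  expect_equal(length(rec$samples), 720L)
  expect_equal(rec$samples, x / 200)               # gain 200, baseline 0
  expect_equal(rec$annotations$sample_index, c(101L, 461L))
  expect_equal(rec$annotations$label, c("normal", "abnormal"))
})

test_that("WFDB reader decodes format 212 byte packing", {
  dir <- withr::local_tempdir()
  # hand-computed packing of the pair (5, -3):
  # 5 -> 0x005, -3 -> 0xFFD; bytes 0x05, 0xF0, 0xFD
  writeLines(c("f212 1 360 2", "f212.dat 212 200(0) 12 0 0 0 0 ch1"),
             file.path(dir, "f212.hea"))
  writeBin(as.raw(c(0x05, 0xF0, 0xFD)), file.path(dir, "f212.dat"))
  rec <- read_wfdb_record(file.path(dir, "f212"), channel = 1)
  expect_equal(rec$samples * 200, c(5, -3))

  # round trip through the fixture writer, two interleaved channels
  ch1 <- as.integer(round(100 * sin(seq(0, 20, length.out = 500))))
  ch2 <- as.integer(round(50 * cos(seq(0, 20, length.out = 500))))
  base <- write_wfdb_fixture(dir, "fix212", list(ch1, ch2), fs = 360,
                             fmt = 212L)
  expect_equal(read_wfdb_record(base, 1)$samples * 200, ch1)
  expect_equal(read_wfdb_record(base, 2)$samples * 200, ch2)
})

test_that("WFDB reader fails cleanly on bad input", {
  dir <- withr::local_tempdir()
  expect_error(read_wfdb_record(file.path(dir, "nope")), "nope.hea")
  base <- write_wfdb_fixture(dir, "one", list(1:10), fs = 360)
  expect_error(read_wfdb_record(base, channel = 3), "out of range")
})

test_that("every WFDB beat code collapses to exactly one binary label", {
  dir <- withr::local_tempdir()
  codes <- c(1L, 2L, 5L, 6L, 8L, 12L, 13L, 38L)   # N L V F A / Q f
  base <- write_wfdb_fixture(dir, "codes", list(rep(0L, 1000L)), fs = 360,
                             ann = data.frame(time = seq(50L, by = 100L,
                                                         length.out = length(codes)),
                                              code = codes))
  rec <- read_wfdb_record(base)
  expect_equal(nrow(rec$annotations), length(codes))
  expect_equal(rec$annotations$label,
               c("normal", rep("abnormal", length(codes) - 1L)))
  # non-beat codes (rhythm 28, artifact 16) are dropped
  base2 <- write_wfdb_fixture(dir, "nonbeat", list(rep(0L, 1000L)), fs = 360,
                              ann = data.frame(time = c(50L, 150L, 250L),
                                               code = c(28L, 1L, 16L)))
  rec2 <- read_wfdb_record(base2)
  expect_equal(rec2$annotations$sample_index, 151L)
})
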