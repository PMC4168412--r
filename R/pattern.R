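#' PQRST window geometry
#'
#' The beat window opens 220 ms before the R-peak and closes 380 ms after
#' it. Sample counts are `ceiling(ms * fs / 1000)` on each side plus the
#' R sample itself; at 360 Hz this gives 80 + 1 + 137 = 218 samples.
#'
#' @param fs sampling rate in Hz.
#' @param pre_ms window extent before the R-peak, ms.
#' @param post_ms window extent after the R-peak, ms.
#' @return list of class `window_spec` with `n_pre`, `n_post`, `n_total`.
#' @export
window_spec <- function(fs, pre_ms = 220, post_ms = 380) {
  stopifnot(fs > 0, pre_ms > 0, post_ms > 0)
  n_pre <- as.integer(ceiling(pre_ms * fs / 1000))
  n_post <- as.integer(ceiling(post_ms * fs / 1000))
  structure(list(fs = fs, pre_ms = pre_ms, post_ms = post_ms,
                 n_pre = n_pre, n_post = n_post,
                 n_total = n_pre + 1L + n_post),
            class = "window_spec")
}

#' Extract the PQRST window around an R-peak
#'
#' Returns the raw samples `r_index - n_pre .. r_index + n_post`
#' (inclusive). Beats whose window crosses a record boundary are dropped
#' with a warning and `NULL` is returned — in a streaming setting a
#' truncated beat is skipped, not an error.
#'
#' @param record an [ecg_record].
#' @param r_index 1-based R-peak sample index.
#' @param spec a [window_spec] (defaults to the record's fs).
#' @return numeric vector of length `spec$n_total`, or `NULL`.
#' @export
extract_pqrst <- function(record, r_index, spec = window_spec(record$fs)) {
  stopifnot(inherits(record, "ecg_record"), inherits(spec, "window_spec"))
  a <- r_index - spec$n_pre
  b <- r_index + spec$n_post
  if (a < 1L || b > length(record$samples)) {
    warning(sprintf("beat at sample %d dropped: PQRST window out of bounds",
                    r_index), call. = FALSE)
    return(NULL)
  }
  record$samples[a:b]
}

#' Quantize a beat window to A amplitude levels
#'
#' Per-beat min–max normalisation to integer levels `0 .. A-1`:
#' `level[i] = round((x[i] - min) / (max - min) * (A - 1))`. A constant
#' window maps to the middle level `floor(A/2)`. Per-beat normalisation
#' makes matching tolerant to slow gain and baseline drift between beats.
#'
#' @param raw_window numeric vector (one PQRST window).
#' @param A number of amplitude levels (default 81).
#' @param r_index optional source R-peak index, carried for packet
#'   generation.
#' @return list of class `quantized_beat` with integer `levels` in
#'   `0..A-1`, the `raw_window`, `A`, and `r_index`.
#' @export
quantize_beat <- function(raw_window, A = 81L, r_index = NA_integer_) {
  if (!is.numeric(raw_window) || length(raw_window) < 2L) {
    stop("raw_window must be a numeric vector of length >= 2", call. = FALSE)
  }
  A <- as.integer(A)
  stopifnot(A >= 2L)
  lo <- min(raw_window); hi <- max(raw_window)
  if (hi == lo) {
    levels <- rep(A %/% 2L, length(raw_window))
  } else {
    levels <- as.integer(round((raw_window - lo) / (hi - lo) * (A - 1L)))
  }
  structure(list(levels = levels, raw_window = as.numeric(raw_window),
                 A = A, r_index = as.integer(r_index)),
            class = "quantized_beat")
}

#' Train the normal-heartbeat pattern matrix
#'
#' Accumulates an `n_total x A` occupancy matrix from quantized normal
#' beats. For each beat and each time column `i`, the cells at the beat's
#' level and its two vertical neighbours (`level-1`, `level`, `level+1`)
#' are each incremented by 1, but never past the saturation cap of 10;
#' neighbour increments falling outside `0..A-1` are skipped. The +/-1
#' smear is what gives the matcher its amplitude tolerance band. The mean
#' of the raw training windows is kept as the reconstruction template.
#'
#' @param beats list of [quantize_beat()] results, all the same length.
#' @param A number of amplitude levels (must match the beats).
#' @param cap per-cell saturation count.
#' @return object of class `pattern_matrix`: `cells` (`n_total x A`
#'   integer matrix, values 0..cap), `template` (numeric, length
#'   `n_total`), `trained_beats`, `match_min` (a cell supports a match
#'   when its count is more than 7, i.e. >= 8), `classify_threshold`.
#' @export
train_matrix <- function(beats, A = 81L, cap = 10L) {
  if (!is.list(beats) || length(beats) == 0L) {
    stop("need at least one training beat", call. = FALSE)
  }
  lens <- vapply(beats, function(b) length(b$levels), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("training beats have mixed window lengths", call. = FALSE)
  }
  A <- as.integer(A)
  n <- lens[1L]
  cells <- matrix(0L, nrow = n, ncol = A)
  cols <- seq_len(n)
  for (b in beats) {
    if (max(b$levels) > A - 1L || min(b$levels) < 0L) {
      stop("beat levels exceed the matrix amplitude range", call. = FALSE)
    }
    for (off in c(0L, -1L, 1L)) {
      rr <- b$levels + 1L + off          # level 0 lives in matrix column 1
      ok <- rr >= 1L & rr <= A
      idx <- cbind(cols[ok], rr[ok])
      below <- cells[idx] < cap
      if (any(below)) {
        idx <- idx[below, , drop = FALSE]
        cells[idx] <- cells[idx] + 1L
      }
    }
  }
  template <- Reduce(`+`, lapply(beats, `[[`, "raw_window")) / length(beats)
  structure(list(cells = cells, A = A, n_total = n, cap = as.integer(cap),
                 trained_beats = length(beats), match_min = 8L,
                 classify_threshold = 180L, template = template),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("<pattern_matrix> %d x %d cells, %d training beats, %d saturated cells\n",
              x$n_total, x$A, x$trained_beats, sum(x$cells >= x$cap)))
  invisible(x)
}

#' ratePM: count of matched matrix cells for one beat
#'
#' For each time column the beat's quantized level is looked up in the
#' trained matrix; the column counts as matched when that cell's occupancy
#' exceeds 7 (i.e. at least 8 training hits, counting the +/-1 training
#' smear). ratePM is the number of matched columns, between 0 and
#' `n_total` (218 at 360 Hz); a perfectly matching beat against a
#' saturated matrix scores the full 218.
#'
#' @param matrix a [train_matrix()] result.
#' @param beat a [quantize_beat()] result of matching length.
#' @return integer ratePM.
#' @export
compute_ratepm <- function(matrix, beat) {
  stopifnot(inherits(matrix, "pattern_matrix"), inherits(beat, "quantized_beat"))
  if (length(beat$levels) != matrix$n_total) {
    stop("beat window length does not match the pattern matrix", call. = FALSE)
  }
  if (beat$A != matrix$A) {
    stop("beat quantized with a different amplitude resolution", call. = FALSE)
  }
  idx <- cbind(seq_len(matrix$n_total), beat$levels + 1L)
  sum(matrix$cells[idx] >= matrix$match_min)
}

#' Classify a beat from its ratePM
#'
#' ratePM strictly above the threshold (default 180 of 218) is a normal
#' beat (`"N"`); at or below it the beat is abnormal (`"A"`). The
#' threshold leaves a tolerance band for the minor amplitude and phase
#' variation of genuine normal beats.
#'
#' @param ratepm integer ratePM value(s).
#' @param threshold classification threshold.
#' @return character vector of `"N"` / `"A"`.
#' @export
classify_beat <- function(ratepm, threshold = 180L) {
  ifelse(ratepm > threshold, "N", "A")
}

# noise-suppressed signal used for pattern extraction and matching:
# the same 35 Hz low-pass + mains-nulling boxcar front end the R-peak
# detector runs. Matching on this signal keeps ratePM stable under
# wideband noise; transmitted waveforms remain the raw samples.
matching_signal <- function(record, params) {
  moving_average(lowpass_filter(record, params$lp_cutoff), params$ma_width)
}

#' Train a pattern matrix from the start of a record
#'
#' Runs the R-peak detector on the first `train_seconds` of the record
#' (30 s by default — enough normal beats to saturate the trajectory
#' cells), extracts and quantizes every beat whose PQRST window is in
#' bounds, and accumulates the pattern matrix. Quantized patterns are
#' taken from the noise-suppressed (low-pass + moving-average) signal so
#' that matching is not dominated by wideband noise; the reconstruction
#' template is the mean of the raw windows.
#'
#' @param record an [ecg_record], at least `train_seconds` long.
#' @param train_seconds length of the training span, s.
#' @param params [rpeak_params]; defaults for the record's fs.
#' @param spec [window_spec]; defaults for the record's fs.
#' @param A amplitude levels.
#' @return a `pattern_matrix`.
#' @export
train_from_record <- function(record, train_seconds = 30,
                              params = rpeak_params(record$fs),
                              spec = window_spec(record$fs), A = 81L) {
  stopifnot(inherits(record, "ecg_record"))
  n_train <- as.integer(round(train_seconds * record$fs))
  if (length(record$samples) < n_train) {
    stop(sprintf("record too short for %g s of training", train_seconds),
         call. = FALSE)
  }
  sub <- new_ecg_record(record$samples[seq_len(n_train)], record$fs,
                        record$units)
  det <- detect_rpeaks(sub, params)
  filt <- matching_signal(sub, params)
  beats <- list()
  for (p in det$peaks) {
    wf <- suppressWarnings(extract_pqrst(filt, p, spec))
    if (is.null(wf)) next
    qb <- quantize_beat(wf, A, p)
    qb$raw_window <- extract_pqrst(sub, p, spec)  # template stays raw
    beats[[length(beats) + 1L]] <- qb
  }
  if (length(beats) < 2L) {
    stop("training failed: fewer than 2 usable beats in the training span",
         call. = FALSE)
  }
  train_matrix(beats, A = A)
}

#' Serialize a pattern matrix to a binary blob
#'
#' Versioned little-endian layout: magic `"PMX1"`, then `n_total`, `A`,
#' `trained_beats` as unsigned 16-bit integers, the cells row-major
#' (time-major) as unsigned bytes, and the template as 32-bit floats.
#'
#' @param matrix a `pattern_matrix`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_pattern_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pattern_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PMX1"), con)
  writeBin(u16_to_raw(c(matrix$n_total, matrix$A, matrix$trained_beats)), con)
  writeBin(as.raw(as.integer(t(matrix$cells))), con)
  writeBin(as.numeric(matrix$template), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a serialized pattern matrix
#'
#' @param path file written by [write_pattern_matrix()].
#' @return a `pattern_matrix`.
#' @export
read_pattern_matrix <- function(path) {
  b <- readBin(path, what = "raw", n = file.size(path))
  if (length(b) < 10L || rawToChar(b[1:4]) != "PMX1") {
    stop("not a pattern-matrix file (bad magic): ", path, call. = FALSE)
  }
  hdr <- raw_to_u16(b[5:10])
  n <- hdr[1L]; A <- hdr[2L]; tb <- hdr[3L]
  need <- 10L + n * A + 4L * n
  if (length(b) < need) stop("truncated pattern-matrix file: ", path, call. = FALSE)
  cells <- matrix(as.integer(b[11:(10L + n * A)]), nrow = n, ncol = A,
                  byrow = TRUE)
  template <- readBin(b[(10L + n * A + 1L):need], what = "numeric", n = n,
                      size = 4L, endian = "little")
  structure(list(cells = cells, A = A, n_total = n, cap = 10L,
                 trained_beats = tb, match_min = 8L,
                 classify_threshold = 180L, template = template),
            class = "pattern_matrix")
}
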