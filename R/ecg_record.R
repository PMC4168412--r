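#' Single-lead ECG record
#'
#' The core container of the package: a sampled single-lead ECG with its
#' sampling rate, amplitude units, and optional reference beat annotations.
#'
#' Samples are either raw 10-bit ADC counts (`units = "adc"`, values in
#' 0--1023) or physical millivolts (`units = "mV"`). Annotations mark
#' reference R-peak positions with a binary `normal`/`abnormal` label;
#' per-type arrhythmia classes are deliberately collapsed because the
#' downstream classifier is binary.
#'
#' @param samples numeric vector of amplitude values, non-empty.
#' @param fs sampling rate in Hz, > 0.
#' @param units `"adc"` (10-bit counts, 0--1023) or `"mV"`.
#' @param annotations optional `data.frame` with columns `sample_index`
#'   (1-based R-peak sample positions, ascending, within the record) and
#'   `label` (`"normal"` or `"abnormal"`).
#' @return an object of class `ecg_record`: a list with fields `samples`,
#'   `fs`, `units`, `annotations`.
#' @examples
#' rec <- ecg_record(c(10, 500, 1000), fs = 360)
#' rec$fs
#' @export
ecg_record <- function(samples, fs, units = c("adc", "mV"), annotations = NULL) {
  units <- match.arg(units)
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (units == "adc") {
    if (any(samples < 0 | samples > 1023)) {
      stop("ADC samples must lie in [0, 1023] (10-bit range)", call. = FALSE)
    }
  }
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations, length(samples))
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, units = units,
         annotations = annotations),
    class = "ecg_record"
  )
}

# internal constructor without the ADC range check, for filter outputs
new_ecg_record <- function(samples, fs, units, annotations = NULL) {
  structure(
    list(samples = as.numeric(samples), fs = fs, units = units,
         annotations = annotations),
    class = "ecg_record"
  )
}

validate_annotations <- function(ann, n_samples) {
  if (!is.data.frame(ann) || !all(c("sample_index", "label") %in% names(ann))) {
    stop("annotations must be a data.frame with columns sample_index, label",
         call. = FALSE)
  }
  idx <- as.integer(ann$sample_index)
  if (any(idx < 1L | idx > n_samples)) {
    stop("annotation sample_index out of record bounds", call. = FALSE)
  }
  if (is.unsorted(idx, strictly = FALSE)) {
    ord <- order(idx)
    ann <- ann[ord, , drop = FALSE]
    idx <- idx[ord]
  }
  lab <- as.character(ann$label)
  if (!all(lab %in% c("normal", "abnormal"))) {
    stop("annotation labels must be 'normal' or 'abnormal'", call. = FALSE)
  }
  data.frame(sample_index = idx, label = lab, stringsAsFactors = FALSE)
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s), units=%s\n",
              length(x$samples), x$fs, dur, x$units))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotated beats (%d abnormal)\n",
                nrow(x$annotations),
                sum(x$annotations$label == "abnormal")))
  }
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' Read a one-column CSV sample stream
#'
#' Reads a plain text signal: one numeric amplitude per line, with an
#' optional single header line. The sampling rate is not stored in the file
#' and must be supplied.
#'
#' @param path file to read.
#' @param fs sampling rate in Hz.
#' @param units amplitude units of the stored values.
#' @return an [ecg_record] without annotations.
#' @export
read_csv_signal <- function(path, fs, units = c("adc", "mV")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty signal file: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1L]) && length(lines) > 1L) {
    # header line
    lines <- lines[-1L]
    vals <- suppressWarnings(as.numeric(lines))
  }
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value at line %d of %s: '%s'",
                 bad[1L], path, lines[bad[1L]]), call. = FALSE)
  }
  ecg_record(vals, fs = fs, units = units)
}

#' Write an ECG record as a one-column CSV
#'
#' Integer ADC data is written losslessly; millivolt data is written with
#' enough significant digits to round-trip through [read_csv_signal()].
#'
#' @param record an [ecg_record].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_csv_signal <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  if (all(x == round(x))) {
    lines <- sprintf("%d", as.integer(round(x)))
  } else {
    lines <- sprintf("%.10g", x)
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write signal file: ", path, call. = FALSE)
  invisible(path)
}

#' Write beat annotations as CSV
#'
#' @param record an [ecg_record] carrying annotations.
#' @param path file to write (columns `sample_index,label`).
#' @return `path`, invisibly.
#' @export
write_csv_annotations <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.null(record$annotations)) stop("record carries no annotations", call. = FALSE)
  utils::write.csv(record$annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read beat annotations from CSV
#'
#' @param path CSV with columns `sample_index,label`.
#' @return data.frame of annotations.
#' @export
read_csv_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(sample_index = as.integer(ann$sample_index),
             label = as.character(ann$label), stringsAsFactors = FALSE)
}
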