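#' Read a PhysioNet WFDB record
#'
#' Minimal reader for WFDB header/signal/annotation triples as used by the
#' MIT-BIH Arrhythmia Database: text `.hea` headers, signal files in format
#' 16 (little-endian int16) or format 212 (packed 12-bit pairs), and MIT
#' format annotation files (e.g. `.atr`).
#'
#' Samples are converted to millivolts using the per-signal gain and
#' baseline from the header (MIT-BIH stores 11-bit ADC counts, so the raw
#' counts do not fit the package's 10-bit `adc` convention). If an
#' annotation file is present, every beat annotation is collapsed to a
#' binary label: code `N` (WFDB code 1) maps to `normal`, every other beat
#' code (PVC, APC, LBBB, fusion, escape, paced, ...) maps to `abnormal`,
#' and non-beat annotations (rhythm changes, artifacts, comments) are
#' dropped.
#'
#' @param path record path without extension (e.g. `"data/100"`).
#' @param channel 1-based signal channel to extract (MIT-BIH channel 1 is
#'   the modified lead II).
#' @param annotator annotation file extension to look for; `NULL` skips
#'   annotations.
#' @return an [ecg_record] in mV with annotations when available.
#' @export
read_wfdb_record <- function(path, channel = 1L, annotator = "atr") {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) {
    stop("WFDB header not found: ", hea_path, call. = FALSE)
  }
  hdr <- parse_wfdb_header(hea_path)
  channel <- as.integer(channel)
  if (channel < 1L || channel > hdr$nsig) {
    stop(sprintf("channel %d out of range (record has %d signals)",
                 channel, hdr$nsig), call. = FALSE)
  }
  sig <- hdr$signals[[channel]]
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path)) {
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  }
  # all signals sharing one .dat are sample-interleaved
  in_file <- which(vapply(hdr$signals, function(s) s$file == sig$file, logical(1)))
  nsig_file <- length(in_file)
  lane <- match(channel, in_file)
  counts <- read_wfdb_samples(dat_path, sig$format, hdr$nsamp * nsig_file)
  counts <- counts[seq(lane, length(counts), by = nsig_file)]
  mv <- (counts - sig$baseline) / sig$gain

  ann <- NULL
  if (!is.null(annotator)) {
    atr_path <- paste0(path, ".", annotator)
    if (file.exists(atr_path)) {
      ann <- read_wfdb_annotations(atr_path, n_samples = length(mv))
    }
  }
  ecg_record(mv, fs = hdr$fs, units = "mV", annotations = ann)
}

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(top[2L])
  fs <- 250
  if (length(top) >= 3L) {
    # fs field may carry counter frequency: "360/21600" or "360(0)"
    fs <- as.numeric(sub("[(/].*$", "", top[3L]))
  }
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  signals <- vector("list", nsig)
  for (k in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1L + k]), "\\s+")[[1L]]
    fmt <- as.integer(sub("x.*$", "", f[2L]))  # strip samples-per-frame
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- NA_real_
    bm <- regmatches(gain_field, regexpr("\\(-?[0-9]+\\)", gain_field))
    if (length(bm) == 1L) baseline <- as.numeric(gsub("[()]", "", bm))
    adczero <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else 0
    if (is.na(baseline)) baseline <- if (is.finite(adczero)) adczero else 0
    signals[[k]] <- list(file = f[1L], format = fmt, gain = gain,
                         baseline = baseline)
  }
  if (is.na(nsamp)) {
    stop("WFDB header lacks a sample count: ", hea_path, call. = FALSE)
  }
  list(nsig = nsig, fs = fs, nsamp = nsamp, signals = signals)
}

read_wfdb_samples <- function(dat_path, format, n_total) {
  if (format == 16L) {
    v <- readBin(dat_path, what = "integer", n = n_total, size = 2L,
                 signed = TRUE, endian = "little")
    if (length(v) < n_total) {
      stop("truncated WFDB signal file: ", dat_path, call. = FALSE)
    }
    return(as.numeric(v))
  }
  if (format == 212L) {
    nbytes <- ceiling(n_total / 2) * 3L
    b <- readBin(dat_path, what = "raw", n = nbytes)
    if (length(b) < nbytes) {
      stop("truncated WFDB signal file: ", dat_path, call. = FALSE)
    }
    b <- as.integer(b)
    b0 <- b[c(TRUE, FALSE, FALSE)]
    b1 <- b[c(FALSE, TRUE, FALSE)]
    b2 <- b[c(FALSE, FALSE, TRUE)]
    s1 <- b0 + 256L * (b1 %% 16L)     # low nibble of middle byte
    s2 <- b2 + 256L * (b1 %/% 16L)    # high nibble of middle byte
    # 12-bit two's complement sign extension
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))[seq_len(n_total)]
    return(as.numeric(v))
  }
  stop("unsupported WFDB signal format: ", format, call. = FALSE)
}

# WFDB annotation codes that denote beats; code 1 is the normal beat.
# Everything else in this set (bundle branch blocks, premature beats,
# fusion, escape, paced, unknown) is treated as abnormal.
wfdb_beat_codes <- c(1:13, 25L, 34L, 35L, 38L, 41L)

read_wfdb_annotations <- function(atr_path, n_samples = Inf) {
  b <- readBin(atr_path, what = "raw", n = file.size(atr_path))
  v <- as.integer(b)
  n <- length(v) %/% 2L
  t_cur <- 0L
  idx <- integer(0); code <- integer(0)
  i <- 1L
  while (i <= n) {
    lo <- v[2L * i - 1L]; hi <- v[2L * i]
    a <- lo + 256L * hi
    cd <- a %/% 1024L
    delta <- a %% 1024L
    i <- i + 1L
    if (cd == 0L && delta == 0L) break                       # EOF
    if (cd == 59L) {                                         # SKIP: 4-byte interval
      if (delta == 0L && i + 1L <= n) {
        hi16 <- v[2L * i - 1L] + 256L * v[2L * i]
        lo16 <- v[2L * (i + 1L) - 1L] + 256L * v[2L * (i + 1L)]
        t_cur <- t_cur + hi16 * 65536L + lo16
        i <- i + 2L
      }
      next
    }
    if (cd %in% c(60L, 61L, 62L)) next                       # NUM/SUB/CHN
    if (cd == 63L) {                                         # AUX string
      nbytes <- delta + delta %% 2L
      i <- i + nbytes %/% 2L
      next
    }
    t_cur <- t_cur + delta
    idx <- c(idx, t_cur)
    code <- c(code, cd)
  }
  beat <- code %in% wfdb_beat_codes
  idx <- idx[beat]; code <- code[beat]
  keep <- idx >= 0L & (idx + 1L) <= n_samples
  idx <- idx[keep]; code <- code[keep]
  if (length(idx) == 0L) return(NULL)
  data.frame(
    sample_index = idx + 1L,     # WFDB times are 0-based sample counts
    label = ifelse(code == 1L, "normal", "abnormal"),
    stringsAsFactors = FALSE
  )
}
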