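#' Construct a wire packet
#'
#' Three packet kinds make up a telemetry stream: one leading template
#' packet `T` (sampling rate + the normal-beat template waveform), a
#' 4-byte `N` packet per normal beat (beat type, preRR, ratePM — no
#' waveform), and a full `A` packet per abnormal beat carrying its raw
#' PQRST window.
#'
#' @param kind `"T"`, `"N"` or `"A"`.
#' @param preRR_ms RR interval preceding the beat, ms (0..65535; N/A
#'   packets only).
#' @param ratePM the beat's ratePM (0..255; N/A packets only).
#' @param payload integer ADC samples 0..1023 (`T`: template; `A`: beat
#'   window; `N`: none).
#' @param fs sampling rate in Hz (`T` only).
#' @return list of class `ecg_packet`.
#' @export
ecg_packet <- function(kind, preRR_ms = NULL, ratePM = NULL, payload = NULL,
                       fs = NULL) {
  if (!kind %in% c("T", "N", "A")) stop("unknown packet kind: ", kind, call. = FALSE)
  if (kind == "T") {
    stopifnot(!is.null(fs), !is.null(payload))
    p <- list(kind = "T", fs = as.integer(fs),
              payload = as.integer(round(payload)))
  } else {
    stopifnot(!is.null(preRR_ms), !is.null(ratePM))
    p <- list(kind = kind, preRR_ms = as.integer(round(preRR_ms)),
              ratePM = as.integer(ratePM))
    if (kind == "A") {
      stopifnot(!is.null(payload))
      p$payload <- as.integer(round(payload))
    } else if (!is.null(payload)) {
      stop("N packets carry no payload", call. = FALSE)
    }
  }
  structure(p, class = "ecg_packet")
}

check_adc_payload <- function(x) {
  if (any(x < 0L | x > 1023L)) {
    stop("payload samples must be 10-bit ADC values in [0, 1023]",
         call. = FALSE)
  }
}

#' Encode one packet to bytes
#'
#' Little-endian layouts (sizes in bytes):
#' \itemize{
#'   \item `N`: `0x4E | preRR u16 | ratePM u8` — 4 bytes
#'   \item `A`: `0x41 | preRR u16 | ratePM u8 | len u16 | len x u16` — 6 + 2*len
#'   \item `T`: `0x54 | fs u16 | len u16 | len x u16` — 5 + 2*len
#' }
#' Waveform samples travel as 10-bit ADC counts in unsigned 16-bit slots
#' (2 bytes per sample).
#'
#' @param p an [ecg_packet].
#' @return raw vector.
#' @export
encode_packet <- function(p) {
  stopifnot(inherits(p, "ecg_packet"))
  if (p$kind == "N") {
    if (p$preRR_ms < 0L || p$preRR_ms > 65535L) stop("preRR out of u16 range", call. = FALSE)
    if (p$ratePM < 0L || p$ratePM > 255L) stop("ratePM out of u8 range", call. = FALSE)
    return(c(as.raw(0x4E), u16_to_raw(p$preRR_ms), as.raw(p$ratePM)))
  }
  if (p$kind == "A") {
    if (p$preRR_ms < 0L || p$preRR_ms > 65535L) stop("preRR out of u16 range", call. = FALSE)
    if (p$ratePM < 0L || p$ratePM > 255L) stop("ratePM out of u8 range", call. = FALSE)
    check_adc_payload(p$payload)
    return(c(as.raw(0x41), u16_to_raw(p$preRR_ms), as.raw(p$ratePM),
             u16_to_raw(length(p$payload)), u16_to_raw(p$payload)))
  }
  # T
  check_adc_payload(p$payload)
  c(as.raw(0x54), u16_to_raw(p$fs), u16_to_raw(length(p$payload)),
    u16_to_raw(p$payload))
}

#' Decode one packet from a byte buffer
#'
#' Exact inverse of [encode_packet()]. Framing is self-describing: each
#' packet states its own payload length, so a decoder never needs to
#' resynchronise.
#'
#' @param buf raw vector.
#' @param offset 1-based offset of the packet's first byte.
#' @return list with the decoded `packet` and `next_offset`.
#' @export
decode_packet <- function(buf, offset = 1L) {
  n <- length(buf)
  if (offset < 1L || offset > n) stop("decode offset outside buffer", call. = FALSE)
  need <- function(k) {
    if (offset + k - 1L > n) {
      stop(sprintf("framing error: truncated packet at offset %d", offset),
           call. = FALSE)
    }
  }
  kind_byte <- as.integer(buf[offset])
  if (kind_byte == 0x4E) {
    need(4L)
    p <- ecg_packet("N",
                    preRR_ms = raw_to_u16(buf[(offset + 1L):(offset + 2L)]),
                    ratePM = as.integer(buf[offset + 3L]))
    return(list(packet = p, next_offset = offset + 4L))
  }
  if (kind_byte == 0x41) {
    need(6L)
    len <- raw_to_u16(buf[(offset + 4L):(offset + 5L)])
    need(6L + 2L * len)
    payload <- raw_to_u16(buf[(offset + 6L):(offset + 5L + 2L * len)])
    p <- ecg_packet("A",
                    preRR_ms = raw_to_u16(buf[(offset + 1L):(offset + 2L)]),
                    ratePM = as.integer(buf[offset + 3L]),
                    payload = payload)
    return(list(packet = p, next_offset = offset + 6L + 2L * len))
  }
  if (kind_byte == 0x54) {
    need(5L)
    len <- raw_to_u16(buf[(offset + 3L):(offset + 4L)])
    need(5L + 2L * len)
    payload <- raw_to_u16(buf[(offset + 5L):(offset + 4L + 2L * len)])
    p <- ecg_packet("T",
                    fs = raw_to_u16(buf[(offset + 1L):(offset + 2L)]),
                    payload = payload)
    return(list(packet = p, next_offset = offset + 5L + 2L * len))
  }
  stop(sprintf("framing error: unknown packet kind byte 0x%02X at offset %d",
               kind_byte, offset), call. = FALSE)
}

#' Encode a packet list to one byte stream
#' @param packets list of [ecg_packet] objects.
#' @return raw vector (concatenated encodings).
#' @export
encode_stream <- function(packets) {
  do.call(c, lapply(packets, encode_packet))
}

#' Decode a whole byte stream back to a packet list
#' @param buf raw vector of concatenated packets.
#' @return list of [ecg_packet] objects.
#' @export
decode_stream <- function(buf) {
  packets <- list()
  offset <- 1L
  while (offset <= length(buf)) {
    d <- decode_packet(buf, offset)
    packets[[length(packets) + 1L]] <- d$packet
    offset <- d$next_offset
  }
  packets
}

# map a record's samples to 10-bit ADC counts; identity for adc records
adc_mapping <- function(record) {
  if (record$units == "adc") {
    return(list(gain = 1, offset = 0))
  }
  lo <- min(record$samples); hi <- max(record$samples)
  if (hi == lo) hi <- lo + 1
  list(gain = 1023 / (hi - lo), offset = -lo * 1023 / (hi - lo))
}

to_adc <- function(x, map) {
  pmin(1023L, pmax(0L, as.integer(round(x * map$gain + map$offset))))
}

#' Generate the telemetry packet stream for a record
#'
#' The transmitter side: detects R-peaks, scores each beat's ratePM
#' against the trained matrix, and emits the template packet followed by
#' a 4-byte `N` packet per normal beat and a full-waveform `A` packet per
#' abnormal beat. Beats inside the first `skip_seconds` (the training
#' span) are not transmitted; beats whose PQRST window crosses a record
#' boundary are skipped.
#'
#' Millivolt records are affinely mapped onto the 0--1023 ADC range of
#' the wire format; the mapping is kept in the returned stream object.
#'
#' @param record an [ecg_record].
#' @param matrix a trained `pattern_matrix`.
#' @param params [rpeak_params].
#' @param spec [window_spec].
#' @param threshold ratePM classification threshold (defaults to the
#'   matrix's stored threshold, 180).
#' @param skip_seconds leading span to exclude from transmission, s.
#' @return object of class `packet_stream`: `packets`, `byte_size`,
#'   `anchor` (R-peak sample index of the first transmitted beat),
#'   `fs`, `beat_log` (per-beat peak, preRR, ratePM, class), and the
#'   ADC mapping.
#' @export
generate_stream <- function(record, matrix,
                            params = rpeak_params(record$fs),
                            spec = window_spec(record$fs),
                            threshold = matrix$classify_threshold,
                            skip_seconds = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (!inherits(matrix, "pattern_matrix") || matrix$trained_beats < 1L) {
    stop("pattern matrix is not trained", call. = FALSE)
  }
  map <- adc_mapping(record)
  det <- detect_rpeaks(record, params)
  filt <- matching_signal(record, params)
  first_tx <- skip_seconds * record$fs
  packets <- list(ecg_packet("T", fs = as.integer(round(record$fs)),
                             payload = to_adc(matrix$template, map)))
  log_peak <- integer(0); log_rr <- integer(0)
  log_pm <- integer(0); log_class <- character(0)
  prev_peak <- NA_integer_
  for (k in seq_along(det$peaks)) {
    p <- det$peaks[k]
    if (p <= first_tx) { prev_peak <- p; next }
    w <- suppressWarnings(extract_pqrst(record, p, spec))
    if (is.null(w)) { prev_peak <- p; next }
    qb <- quantize_beat(extract_pqrst(filt, p, spec), matrix$A, p)
    pm <- compute_ratepm(matrix, qb)
    cls <- classify_beat(pm, threshold)
    rr <- if (is.na(prev_peak)) 0L else as.integer(round((p - prev_peak) * 1000 / record$fs))
    pm_u8 <- min(pm, 255L)
    if (cls == "N") {
      pkt <- ecg_packet("N", preRR_ms = rr, ratePM = pm_u8)
    } else {
      pkt <- ecg_packet("A", preRR_ms = rr, ratePM = pm_u8,
                        payload = to_adc(w, map))
    }
    packets[[length(packets) + 1L]] <- pkt
    log_peak <- c(log_peak, p); log_rr <- c(log_rr, rr)
    log_pm <- c(log_pm, pm); log_class <- c(log_class, cls)
    prev_peak <- p
  }
  encoded <- encode_stream(packets)
  structure(list(packets = packets, byte_size = length(encoded),
                 anchor = if (length(log_peak)) log_peak[1L] else NA_integer_,
                 fs = record$fs, spec = spec,
                 adc_gain = map$gain, adc_offset = map$offset,
                 beat_log = data.frame(peak = log_peak, preRR_ms = log_rr,
                                       ratePM = log_pm, class = log_class,
                                       stringsAsFactors = FALSE)),
            class = "packet_stream")
}

#' @export
print.packet_stream <- function(x, ...) {
  kinds <- vapply(x$packets, `[[`, character(1), "kind")
  cat(sprintf("<packet_stream> %d packets (%d N, %d A), %d bytes\n",
              length(x$packets), sum(kinds == "N"), sum(kinds == "A"),
              x$byte_size))
  invisible(x)
}

#' Write an encoded packet stream to a file
#' @param stream a `packet_stream` or list of packets.
#' @param path file to write (conventionally `.ecgpkt`).
#' @return `path`, invisibly.
#' @export
write_packet_stream <- function(stream, path) {
  packets <- if (inherits(stream, "packet_stream")) stream$packets else stream
  writeBin(encode_stream(packets), path)
  invisible(path)
}

#' Read an encoded packet stream from a file
#' @param path file written by [write_packet_stream()].
#' @return list of [ecg_packet] objects.
#' @export
read_packet_stream <- function(path) {
  decode_stream(readBin(path, what = "raw", n = file.size(path)))
}
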