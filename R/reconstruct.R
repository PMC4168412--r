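#' Reconstruct an ECG signal from a packet stream
#'
#' The receiver side: the stream must begin with a `T` packet carrying
#' the normal-beat template. For every subsequent beat packet a PQRST
#' window is laid down on the output time base — the stored template for
#' `N` beats, the transmitted waveform for `A` beats — with its R sample
#' at the position implied by the accumulated preRR intervals: the first
#' beat's R lands at `anchor`, and each later beat at the previous R plus
#' its decoded preRR (converted to samples and rounded).
#'
#' Gaps between consecutive windows are filled by linear interpolation
#' between the adjacent window edge samples; when a premature beat's
#' window overlaps the previous one, the later window overwrites from its
#' first sample.
#'
#' @param stream a `packet_stream` from [generate_stream()], or a list of
#'   packets from [decode_stream()] (first packet must be `T`).
#' @param anchor sample index at which the first beat's R-peak is placed;
#'   defaults to the stream's recorded anchor so the reconstruction is on
#'   the original record's time base.
#' @param pre_ms,post_ms window extents used to centre each waveform on
#'   its R sample (the template layout convention).
#' @return object of class `reconstructed_signal`: `samples` (ADC
#'   units, index 1 = original record's sample 1), `fs`, `beat_log`
#'   (`kind`, `r_position`, `ratePM`), `covered_from`/`covered_to` (span
#'   actually carried by beat windows).
#' @export
reconstruct_signal <- function(stream, anchor = NULL, pre_ms = 220,
                               post_ms = 380) {
  if (inherits(stream, "packet_stream")) {
    packets <- stream$packets
    if (is.null(anchor)) anchor <- stream$anchor
  } else {
    packets <- stream
  }
  if (length(packets) == 0L || packets[[1L]]$kind != "T") {
    stop("packet stream must begin with a template (T) packet", call. = FALSE)
  }
  tpkt <- packets[[1L]]
  fs <- tpkt$fs
  template <- tpkt$payload
  spec <- window_spec(fs, pre_ms, post_ms)
  if (length(template) != spec$n_total) {
    stop("template length does not match the window geometry", call. = FALSE)
  }
  beats <- packets[-1L]
  if (length(beats) == 0L) {
    return(structure(list(samples = as.numeric(template), fs = fs,
                          beat_log = data.frame(kind = character(0),
                                                r_position = integer(0),
                                                ratePM = integer(0)),
                          covered_from = 1L,
                          covered_to = length(template)),
                     class = "reconstructed_signal"))
  }
  if (is.null(anchor) || is.na(anchor)) anchor <- spec$n_pre + 1L
  kinds <- vapply(beats, `[[`, character(1), "kind")
  if (any(!kinds %in% c("N", "A"))) {
    stop("beat packets must be N or A", call. = FALSE)
  }
  rr <- vapply(beats, `[[`, integer(1), "preRR_ms")
  r_pos <- anchor + c(0L, as.integer(round(cumsum(rr[-1L] * fs / 1000))))

  n_out <- max(r_pos) + spec$n_post
  out <- rep(NA_real_, n_out)
  for (k in seq_along(beats)) {
    w <- if (kinds[k] == "N") template else beats[[k]]$payload
    a <- r_pos[k] - spec$n_pre
    b <- r_pos[k] + spec$n_post
    src_from <- 1L + max(0L, 1L - a)
    a <- max(1L, a)
    out[a:b] <- w[src_from:length(w)]
  }
  covered_from <- max(1L, r_pos[1L] - spec$n_pre)
  # linear interpolation across gaps, edge values extended at the ends
  out <- zoo::na.approx(out, na.rm = FALSE, rule = 2)
  structure(list(samples = out, fs = fs,
                 beat_log = data.frame(kind = kinds, r_position = r_pos,
                                       ratePM = vapply(beats, `[[`, integer(1), "ratePM"),
                                       stringsAsFactors = FALSE),
                 covered_from = covered_from, covered_to = n_out),
            class = "reconstructed_signal")
}

#' @export
print.reconstructed_signal <- function(x, ...) {
  cat(sprintf("<reconstructed_signal> %d samples @ %g Hz, %d beats (%d abnormal)\n",
              length(x$samples), x$fs, nrow(x$beat_log),
              sum(x$beat_log$kind == "A")))
  invisible(x)
}
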