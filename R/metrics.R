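#' Compression ratio
#'
#' Ratio of the bytes a conventional transmitter would send (2 bytes per
#' 10-bit sample) to the bytes actually transmitted.
#'
#' @param raw_bytes conventional byte count (> 0).
#' @param tx_bytes transmitted byte count (> 0).
#' @return the exact quotient `raw_bytes / tx_bytes`.
#' @export
compression_ratio <- function(raw_bytes, tx_bytes) {
  if (!is.numeric(tx_bytes) || any(tx_bytes <= 0)) {
    stop("transmitted byte count must be positive", call. = FALSE)
  }
  raw_bytes / tx_bytes
}

#' Correlation and RMSE between original and reconstructed signals
#'
#' Both signals are min–max normalised to `[0, 1]` over the compared
#' span, then the Pearson correlation coefficient and the root mean
#' square difference are computed, so the RMSE is on a 0--1 amplitude
#' scale regardless of the input units.
#'
#' @param original numeric vector or [ecg_record].
#' @param recon numeric vector or `reconstructed_signal`.
#' @param fs sampling rate, used only to enforce a minimum 1 s overlap;
#'   taken from the inputs when available.
#' @return list with `cc` and `rmse`.
#' @export
correlation_and_rmse <- function(original, recon, fs = NULL) {
  if (inherits(original, "ecg_record")) {
    if (is.null(fs)) fs <- original$fs
    original <- original$samples
  }
  if (inherits(recon, "reconstructed_signal")) {
    if (is.null(fs)) fs <- recon$fs
    recon <- recon$samples
  }
  n <- min(length(original), length(recon))
  if (!is.null(fs) && n < fs) {
    stop("signals overlap for less than 1 s", call. = FALSE)
  }
  x <- original[seq_len(n)]
  y <- recon[seq_len(n)]
  norm01 <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) stop("zero-variance signal: correlation undefined", call. = FALSE)
    (v - lo) / (hi - lo)
  }
  x <- norm01(x); y <- norm01(y)
  list(cc = stats::cor(x, y), rmse = sqrt(mean((x - y)^2)))
}

#' R-peak detection accuracy
#'
#' Greedy one-to-one matching of detected peaks to reference peaks
#' within a time tolerance; accuracy is the percentage of reference
#' beats matched.
#'
#' @param detected ascending detected R-peak sample indices.
#' @param reference ascending reference R-peak sample indices (non-empty).
#' @param fs sampling rate in Hz.
#' @param tol_ms matching tolerance, ms.
#' @return percentage in `[0, 100]`.
#' @export
rpeak_accuracy <- function(detected, reference, fs, tol_ms = 50) {
  if (length(reference) == 0L) {
    stop("reference peak list is empty", call. = FALSE)
  }
  tol <- tol_ms / 1000 * fs
  m <- match_events(detected, reference, tol)
  100 * sum(!is.na(m$detected)) / length(reference)
}

#' Abnormal-beat detection accuracy
#'
#' Pairs classified beats with reference annotations by R position
#' (greedy matching within `tol_ms`), then reports the percentage of
#' reference-abnormal beats whose paired beat was classified `A` (true
#' positives over truth). Over-detection does not inflate the accuracy;
#' false alarms (reference-normal beats classified `A`) are counted
#' separately.
#'
#' @param beat_log data.frame with columns `peak` (or `r_position`) and
#'   `class` (`"N"`/`"A"`), e.g. a stream or reconstruction beat log.
#' @param reference annotation data.frame (`sample_index`, `label`).
#' @param fs sampling rate in Hz.
#' @param tol_ms pairing tolerance, ms.
#' @return list with `accuracy_pct` (`NA` when the reference has no
#'   abnormal beats), `n_reference_abnormal`, `n_true_positive`,
#'   `n_detected_abnormal`, `false_alarms`.
#' @export
abnormal_accuracy <- function(beat_log, reference, fs, tol_ms = 50) {
  pos_col <- if ("peak" %in% names(beat_log)) "peak" else "r_position"
  det_pos <- beat_log[[pos_col]]
  det_class <- beat_log$class
  tol <- tol_ms / 1000 * fs
  m <- match_events(det_pos, reference$sample_index, tol)
  paired_class <- rep(NA_character_, nrow(m))
  ok <- !is.na(m$det_pos)
  paired_class[ok] <- det_class[m$det_pos[ok]]
  is_abn <- reference$label == "abnormal"
  n_abn <- sum(is_abn)
  tp <- sum(is_abn & !is.na(paired_class) & paired_class == "A")
  fa <- sum(!is_abn & !is.na(paired_class) & paired_class == "A")
  list(
    accuracy_pct = if (n_abn == 0L) NA_real_ else 100 * tp / n_abn,
    n_reference_abnormal = n_abn,
    n_true_positive = tp,
    n_detected_abnormal = sum(det_class == "A"),
    false_alarms = fa
  )
}

#' Evaluate a transmission end to end
#'
#' Builds the per-record report: compression ratio (conventional
#' 2-bytes-per-sample cost of the transmitted span vs. actual stream
#' bytes), correlation and RMSE between the original and reconstructed
#' signals over the span the reconstruction covers, R-peak detection
#' accuracy and abnormal detection accuracy against the record's
#' reference annotations (restricted to the transmitted span).
#'
#' @param record the original [ecg_record] (annotations optional).
#' @param stream the [generate_stream()] result.
#' @param recon the [reconstruct_signal()] result (computed from
#'   `stream` when omitted).
#' @param tol_ms matching tolerance for beat pairing, ms.
#' @return list of class `eval_report`.
#' @export
evaluate_transmission <- function(record, stream, recon = NULL, tol_ms = 50) {
  stopifnot(inherits(record, "ecg_record"), inherits(stream, "packet_stream"))
  if (is.null(recon)) recon <- reconstruct_signal(stream)
  fs <- record$fs
  span <- recon$covered_from:min(length(record$samples), length(recon$samples))
  raw_bytes <- 2L * length(span)
  cr <- compression_ratio(raw_bytes, stream$byte_size)

  map <- list(gain = stream$adc_gain, offset = stream$adc_offset)
  orig_adc <- record$samples * map$gain + map$offset
  fit <- correlation_and_rmse(orig_adc[span], recon$samples[span], fs = fs)

  rpk <- NA_real_; abn <- NULL
  ann <- record$annotations
  if (!is.null(ann) && nrow(ann) > 0L) {
    in_span <- ann$sample_index >= min(span) & ann$sample_index <= max(span)
    ann_span <- ann[in_span, , drop = FALSE]
    if (nrow(ann_span) > 0L) {
      rpk <- rpeak_accuracy(stream$beat_log$peak, ann_span$sample_index,
                            fs, tol_ms)
      abn <- abnormal_accuracy(stream$beat_log, ann_span, fs, tol_ms)
    }
  }
  structure(list(
    cr = cr, cc = fit$cc, rmse = fit$rmse,
    rpeak_accuracy_pct = rpk,
    abnormal_accuracy_pct = if (is.null(abn)) NA_real_ else abn$accuracy_pct,
    counts = list(
      total_beats_transmitted = nrow(stream$beat_log),
      abnormal_transmitted = sum(stream$beat_log$class == "A"),
      reference_beats = if (is.null(ann)) NA_integer_ else nrow(ann),
      reference_abnormal = if (is.null(abn)) NA_integer_ else abn$n_reference_abnormal,
      true_positive_abnormal = if (is.null(abn)) NA_integer_ else abn$n_true_positive,
      false_alarms = if (is.null(abn)) NA_integer_ else abn$false_alarms
    ),
    raw_bytes = raw_bytes, tx_bytes = stream$byte_size
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  compression ratio : %.2f (%d raw / %d tx bytes)\n",
              x$cr, x$raw_bytes, x$tx_bytes))
  cat(sprintf("  correlation (CC)  : %.3f\n", x$cc))
  cat(sprintf("  RMSE (0-1 scale)  : %.3f\n", x$rmse))
  if (!is.na(x$rpeak_accuracy_pct)) {
    cat(sprintf("  R-peak accuracy   : %.1f%%\n", x$rpeak_accuracy_pct))
  }
  if (!is.na(x$abnormal_accuracy_pct)) {
    cat(sprintf("  abnormal accuracy : %.1f%% (%d/%d, %d false alarms)\n",
                x$abnormal_accuracy_pct, x$counts$true_positive_abnormal,
                x$counts$reference_abnormal, x$counts$false_alarms))
  }
  invisible(x)
}
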