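#' Run the full transmit/receive pipeline on one record
#'
#' End-to-end flow: train the normal-beat pattern matrix on the first
#' `train_seconds` of the record, generate the telemetry packet stream
#' for the remainder (template + 4-byte normal packets + full-waveform
#' abnormal packets), reconstruct the signal on the receiver side, and
#' evaluate compression ratio, correlation/RMSE and detection accuracy
#' against the record's reference annotations when present.
#'
#' @param record an [ecg_record].
#' @param train_seconds training span at the start of the record, s.
#' @param A amplitude levels of the pattern matrix.
#' @param threshold ratePM classification threshold.
#' @param params [rpeak_params]; defaults for the record's fs.
#' @param tol_ms beat-pairing tolerance for the accuracy metrics, ms.
#' @return list of class `pipeline_result` with `matrix`, `stream`,
#'   `recon`, `report`.
#' @examples
#' rec <- synth_ecg(synth_config(duration_s = 60, seed = 1))
#' res <- run_pipeline(rec, train_seconds = 30)
#' res$report
#' @export
run_pipeline <- function(record, train_seconds = 30, A = 81L,
                         threshold = 180L,
                         params = rpeak_params(record$fs), tol_ms = 50) {
  stopifnot(inherits(record, "ecg_record"))
  spec <- window_spec(record$fs)
  matrix <- train_from_record(record, train_seconds = train_seconds,
                              params = params, spec = spec, A = A)
  stream <- generate_stream(record, matrix, params = params, spec = spec,
                            threshold = threshold,
                            skip_seconds = train_seconds)
  recon <- reconstruct_signal(stream)
  report <- evaluate_transmission(record, stream, recon, tol_ms = tol_ms)
  structure(list(matrix = matrix, stream = stream, recon = recon,
                 report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
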