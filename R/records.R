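# Container types shared across the pipeline.

#' Three-axis acceleration trace
#'
#' @param samples Numeric N x 3 matrix of acceleration in g (device axes).
#' @param rate Sampling rate in Hz (125 for the chest patch).
#' @param start_time Numeric start time in seconds (default 0).
#' @return Object of class `accel_trace`.
#' @export
accel_trace <- function(samples, rate = 125, start_time = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3) stop("accel_trace requires an N x 3 matrix")
  if (rate <= 0) stop("rate must be positive")
  structure(list(samples = samples, rate = rate, start_time = start_time),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples x 3 axes @ %g Hz (%.2f h)\n",
              nrow(x$samples), x$rate, nrow(x$samples) / x$rate / 3600))
  invisible(x)
}

#' Single-channel respiratory waveform
#'
#' The derived chest-wall displacement signal (ACC-RESP), a surrogate for
#' a thoracic impedance-pneumography channel. The canonical rate is
#' 307,200 samples per 10 h = 8.5333... Hz, the model's respiratory input
#' grid.
#'
#' @param samples Numeric vector (unitless displacement).
#' @param rate Sampling rate in Hz.
#' @param start_time Numeric start time in seconds.
#' @return Object of class `resp_signal`.
#' @export
resp_signal <- function(samples, rate = RESP_MODEL_HZ, start_time = 0) {
  structure(list(samples = as.numeric(samples), rate = rate,
                 start_time = start_time),
            class = "resp_signal")
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal> %d samples @ %.4f Hz (%.2f h)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate / 3600))
  invisible(x)
}

#' Canonical model input rates (samples per 10-h night / 36,000 s)
#' @export
ECG_MODEL_HZ <- 1228800 / 36000   # 34.1333... Hz

#' @rdname ECG_MODEL_HZ
#' @export
RESP_MODEL_HZ <- 307200 / 36000   # 8.5333... Hz

#' One participant-night of aligned signals and labels
#'
#' @param participant_id Character id.
#' @param night_label One of `B1`, `I1`..`I7`, `F1` (or `NA`).
#' @param ecg Numeric ECG vector at `ecg_rate` Hz (may be `NULL` for
#'   hypnogram-only records).
#' @param accel [accel_trace] or `NULL`.
#' @param hypnogram [hypnogram].
#' @param resp Optional [resp_signal].
#' @param ecg_rate ECG sampling rate in Hz.
#' @param quality_flags Character vector of quality annotations.
#' @param truth Optional list of generator ground truth (synthetic records).
#' @return Object of class `night_record`.
#' @export
night_record <- function(participant_id, night_label, hypnogram,
                         ecg = NULL, accel = NULL, resp = NULL,
                         ecg_rate = 125, quality_flags = character(0),
                         truth = NULL) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  if (!is.null(accel)) stopifnot(inherits(accel, "accel_trace"))
  if (!is.null(resp)) stopifnot(inherits(resp, "resp_signal"))
  structure(list(participant_id = participant_id,
                 night_label = night_label,
                 ecg = ecg, ecg_rate = ecg_rate,
                 accel = accel, resp = resp,
                 hypnogram = hypnogram,
                 quality_flags = quality_flags,
                 truth = truth),
            class = "night_record")
}

#' @export
print.night_record <- function(x, ...) {
  cat(sprintf("<night_record> %s / %s: %d epochs (%.1f h)%s%s%s\n",
              x$participant_id, x$night_label, length(x$hypnogram),
              length(x$hypnogram) * EPOCH_SEC / 3600,
              if (!is.null(x$ecg)) ", ECG" else "",
              if (!is.null(x$accel)) ", ACC" else "",
              if (!is.null(x$resp)) ", RESP" else ""))
  invisible(x)
}
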