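# Alignment, resampling, windowing, and quality screening of nights.

#' Model input grid
#'
#' The staging model consumes fixed-length windows: `n_epochs` 30-s
#' epochs, with `ecg_samples_per_epoch` ECG samples and
#' `resp_samples_per_epoch` respiratory samples per epoch. The canonical
#' grid is 1,200 epochs (10 h) with 1,024 ECG samples/epoch
#' (1,228,800 total @ 34.1333... Hz) and 256 respiratory samples/epoch
#' (307,200 total @ 8.5333... Hz).
#'
#' @param n_epochs Number of epochs per model window.
#' @param ecg_samples_per_epoch ECG samples per epoch (power of 2 times
#'   the per-epoch frame count of the encoder).
#' @param resp_samples_per_epoch Respiratory samples per epoch.
#' @return Object of class `model_grid`.
#' @export
model_grid <- function(n_epochs = 1200, ecg_samples_per_epoch = 1024,
                       resp_samples_per_epoch = 256) {
  stopifnot(n_epochs >= 1,
            ecg_samples_per_epoch %% 1 == 0,
            resp_samples_per_epoch %% 1 == 0)
  structure(list(n_epochs = n_epochs,
                 ecg_samples_per_epoch = ecg_samples_per_epoch,
                 resp_samples_per_epoch = resp_samples_per_epoch,
                 ecg_len = n_epochs * ecg_samples_per_epoch,
                 resp_len = n_epochs * resp_samples_per_epoch,
                 ecg_rate = ecg_samples_per_epoch / EPOCH_SEC,
                 resp_rate = resp_samples_per_epoch / EPOCH_SEC),
            class = "model_grid")
}

#' Robust per-night normalization
#'
#' Subtracts the median and divides by the interquartile range, then
#' clips to +/- `clip`; heavy-tail robust for wearable ECG. A degenerate
#' signal (IQR = 0) returns all zeros with a warning.
#'
#' @param x Numeric vector.
#' @param clip Clip bound after scaling.
#' @return Normalized vector.
#' @export
robust_normalize <- function(x, clip = 10) {
  iqr <- stats::IQR(x, na.rm = TRUE)
  med <- stats::median(x, na.rm = TRUE)
  # degenerate = flat signal: zero IQR, or IQR that is pure numerical
  # ripple relative to the DC level (e.g. a constant channel after
  # polyphase resampling)
  if (!is.finite(iqr) || iqr <= 1e-3 * abs(med)) {
    warning("degenerate signal: IQR is (near) zero; returning zeros")
    return(numeric(length(x)))
  }
  pmin(clip, pmax(-clip, (x - med) / iqr))
}

# Resample to the target rate (exact rational ratio), truncate to the
# window, normalize, then right-pad with zeros to `len` (padding stays
# exactly zero because it is appended after normalization).
fit_to_grid <- function(x, src_rate, tgt_rate_num, tgt_rate_den, len) {
  y <- resample_rational(x, tgt_rate_num, tgt_rate_den * src_rate)
  y <- y[seq_len(min(len, length(y)))]
  y <- robust_normalize(y)
  c(y, numeric(len - length(y)))
}

#' Resample a night onto the model grid
#'
#' Produces the model's fixed-length input: ECG polyphase-resampled to
#' the grid rate and robust-normalized per night; the respiratory channel
#' likewise if present. Nights shorter than the window are right-padded
#' with zeros and `PAD` labels; longer nights are truncated to the first
#' `n_epochs` epochs (sleep onset is kept). The loss mask is `FALSE`
#' wherever the label is `ARTIFACT` or `PAD`.
#'
#' @param night [night_record] with at least ECG and a hypnogram.
#' @param grid [model_grid].
#' @return Object of class `model_input`: list with `ecg`, `resp`
#'   (or `NULL`), `labels` ([hypnogram], length `n_epochs`), `loss_mask`,
#'   `participant_id`, `night_label`.
#' @export
resample_to_model_grid <- function(night, grid = model_grid()) {
  stopifnot(inherits(night, "night_record"), inherits(grid, "model_grid"))
  if (is.null(night$ecg)) stop("night has no ECG channel")
  n_real <- min(length(night$hypnogram), grid$n_epochs)

  ecg <- fit_to_grid(night$ecg[seq_len(min(length(night$ecg),
                                           grid$n_epochs * EPOCH_SEC * night$ecg_rate))],
                     night$ecg_rate, grid$ecg_rate * EPOCH_SEC, EPOCH_SEC,
                     grid$ecg_len)
  resp <- NULL
  if (!is.null(night$resp)) {
    r <- night$resp
    resp <- fit_to_grid(r$samples[seq_len(min(length(r$samples),
                                              round(grid$n_epochs * EPOCH_SEC * r$rate)))],
                        r$rate, grid$resp_rate * EPOCH_SEC, EPOCH_SEC,
                        grid$resp_len)
  }

  labels <- c(as.character(night$hypnogram)[seq_len(n_real)],
              rep("PAD", grid$n_epochs - n_real))
  labels <- hypnogram(labels)
  structure(list(ecg = ecg, resp = resp, labels = labels,
                 loss_mask = is_scoreable(labels),
                 participant_id = night$participant_id,
                 night_label = night$night_label,
                 grid = grid),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat(sprintf("<model_input> %s/%s: ecg %d%s, %d epochs (%d scored)\n",
              x$participant_id, x$night_label, length(x$ecg),
              if (!is.null(x$resp)) sprintf(" + resp %d", length(x$resp)) else "",
              length(x$labels), sum(x$loss_mask)))
  invisible(x)
}

# Longest run of NA in a vector, in samples.
longest_na_run <- function(x) {
  if (!anyNA(x)) return(0L)
  r <- rle(is.na(x))
  max(c(0L, r$lengths[r$values]))
}

#' Night-level quality screen
#'
#' A night fails if any contiguous missing-data run in the ECG or any
#' accelerometer axis exceeds `max_gap_min` minutes (per-gap rule, not a
#' total), or if its hypnogram is entirely `ARTIFACT`.
#'
#' @param night [night_record].
#' @param max_gap_min Maximum tolerated contiguous gap, minutes.
#' @return List with `pass` (logical) and `reasons` (character).
#' @export
night_quality <- function(night, max_gap_min = 30) {
  stopifnot(inherits(night, "night_record"))
  reasons <- character(0)
  gap_limit_ecg <- max_gap_min * 60 * night$ecg_rate
  if (!is.null(night$ecg) && longest_na_run(night$ecg) > gap_limit_ecg) {
    reasons <- c(reasons, "gap>30min")
  }
  if (!is.null(night$accel)) {
    gl <- max_gap_min * 60 * night$accel$rate
    if (any(apply(night$accel$samples, 2, longest_na_run) > gl)) {
      reasons <- c(reasons, "gap>30min")
    }
  }
  if (all(as.character(night$hypnogram) == "ARTIFACT")) {
    reasons <- c(reasons, "all_artifact")
  }
  list(pass = length(reasons) == 0, reasons = unique(reasons))
}

#' Participant inclusion rule
#'
#' A participant is included when usable data are available for at least
#' `min_frac` of their study nights.
#'
#' @param quality_results List of [night_quality()] results (or logical
#'   vector of per-night passes).
#' @param min_frac Minimum passing fraction (default 0.75).
#' @return Logical: include the participant?
#' @export
participant_inclusion <- function(quality_results, min_frac = 0.75) {
  passes <- if (is.logical(quality_results)) quality_results
            else vapply(quality_results, function(q) q$pass, logical(1))
  if (length(passes) == 0) stop("at least one night is required")
  mean(passes) >= min_frac
}

#' Run the signal pipeline over a cohort of night records
#'
#' For each night: derive the ACC-RESP respiratory waveform from the
#' accelerometer (unless `use_resp = FALSE` or no accelerometer is
#' present), then resample everything onto the model grid.
#'
#' @param records List of [night_record] (e.g. [generate_cohort()]).
#' @param grid [model_grid].
#' @param extract_cfg [extraction_config] for respiration derivation.
#' @param use_resp Derive and include the respiratory channel?
#' @return List of `model_input`.
#' @export
cohort_model_inputs <- function(records, grid = model_grid(),
                                extract_cfg = extraction_config(),
                                use_resp = TRUE) {
  lapply(records, function(rec) {
    if (use_resp && !is.null(rec$accel) && is.null(rec$resp)) {
      rec$resp <- extract_resp(rec$accel, extract_cfg)
    }
    if (!use_resp) rec$resp <- NULL
    resample_to_model_grid(rec, grid)
  })
}
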