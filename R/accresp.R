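# ACC-RESP: respiratory waveform derivation from chest accelerometry.

#' Respiration-extraction configuration
#'
#' Free parameters of the accelerometer-to-respiration derivation. Two
#' modes are provided. `GRAVITY_PLANE` is the classical recursive method:
#' the acceleration residual is projected onto the plane perpendicular to
#' the local gravity estimate before a windowed principal-component
#' projection, which makes the method blind to chest-wall motion parallel
#' to gravity (a posture-dependent blind spot: supine respiration is
#' largely gravity-parallel). `ORIENTATION_ROBUST` removes the geometric
#' projection: the quasi-static gravity component is removed by the
#' band-pass high edge alone and the principal axis is found in the full
#' 3-D windowed covariance, so respiratory motion is captured regardless
#' of its angle to gravity.
#'
#' @param window_sec Analysis window length, s (matches the 30-s epoch
#'   timescale).
#' @param overlap_frac Window overlap fraction (0, 1).
#' @param band_low_hz,band_high_hz Respiratory band edges, Hz.
#' @param gravity_lp_hz Gravity low-pass cutoff, Hz.
#' @param mode `"GRAVITY_PLANE"` or `"ORIENTATION_ROBUST"`.
#' @param out_rate_num,out_rate_den Output rate as an exact rational
#'   (default 307,200 samples / 36,000 s = 8.5333... Hz, the model grid).
#' @return Object of class `extraction_config`.
#' @export
extraction_config <- function(window_sec = 30, overlap_frac = 0.5,
                              band_low_hz = 0.08, band_high_hz = 0.8,
                              gravity_lp_hz = 0.04,
                              mode = c("ORIENTATION_ROBUST", "GRAVITY_PLANE"),
                              out_rate_num = 307200, out_rate_den = 36000) {
  mode <- match.arg(mode)
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz)) {
    stop("need 0 < band_low_hz < band_high_hz")
  }
  if (!(overlap_frac > 0 && overlap_frac < 1)) {
    stop("overlap_frac must be in (0, 1)")
  }
  structure(list(window_sec = window_sec, overlap_frac = overlap_frac,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 gravity_lp_hz = gravity_lp_hz, mode = mode,
                 out_rate_num = out_rate_num, out_rate_den = out_rate_den),
            class = "extraction_config")
}

# Zero-phase Butterworth filtering with odd-reflection padding at both
# ends (suppresses the start-up transients zero-padding would create on
# signals with a DC offset, e.g. the ~1 g gravity axis).
filtfilt_padded <- function(flt, col, pad) {
  n <- length(col)
  pad <- min(pad, n - 1)
  if (pad > 0) {
    head_ext <- 2 * col[1] - col[(pad + 1):2]
    tail_ext <- 2 * col[n] - col[(n - 1):(n - pad)]
    y <- as.numeric(signal::filtfilt(flt, c(head_ext, col, tail_ext)))
    y[(pad + 1):(pad + n)]
  } else {
    as.numeric(signal::filtfilt(flt, col))
  }
}

# `pad_sec` should cover a few periods of the filter's lowest corner.
filt_cols <- function(x, flt, rate, pad_sec) {
  apply(x, 2, function(col) filtfilt_padded(flt, col, round(pad_sec * rate)))
}

# Linear interpolation of interior gaps <= max_gap_sec; longer gaps are
# zero-filled. Returns the filled matrix plus a flag.
fill_gaps <- function(x, rate, max_gap_sec = 5) {
  long_gap <- FALSE
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (!anyNA(col)) next
    r <- rle(is.na(col))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      if (r$lengths[k] <= max_gap_sec * rate &&
          starts[k] > 1 && ends[k] < length(col)) {
        i0 <- starts[k] - 1
        i1 <- ends[k] + 1
        col[starts[k]:ends[k]] <-
          seq(col[i0], col[i1], length.out = r$lengths[k] + 2)[-c(1, r$lengths[k] + 2)]
      } else {
        col[starts[k]:ends[k]] <- 0
        long_gap <- TRUE
      }
    }
    x[, j] <- col
  }
  list(x = x, long_gap = long_gap)
}

#' Estimate the gravity direction series
#'
#' Low-passes each accelerometer axis at `cfg$gravity_lp_hz` (zero-phase,
#' second-order Butterworth) and renormalizes each sample to unit length,
#' giving a smooth per-sample unit vector tracking the quasi-static
#' orientation of the device relative to gravity.
#'
#' @param acc [accel_trace].
#' @param cfg [extraction_config].
#' @return N x 3 matrix of unit vectors.
#' @export
estimate_gravity <- function(acc, cfg = extraction_config()) {
  stopifnot(inherits(acc, "accel_trace"))
  x <- acc$samples
  if (nrow(x) < acc$rate / cfg$gravity_lp_hz) {
    stop("trace shorter than one gravity low-pass period")
  }
  lp <- signal::butter(2, cfg$gravity_lp_hz / (acc$rate / 2), type = "low")
  g <- filt_cols(x, lp, acc$rate, 4 / cfg$gravity_lp_hz)
  nrm <- sqrt(rowSums(g^2))
  if (all(nrm < 1e-9)) stop("degenerate gravity: all-zero acceleration trace")
  g / pmax(nrm, 1e-12)
}

# Windowed first-principal-axis projection with sign continuity and
# Hann-weighted overlap-add. `x` is N x 3 (already band-passed; for the
# gravity-plane mode, already projected in-plane). Returns length-N signal.
principal_axis_ola <- function(x, rate, window_sec, overlap_frac) {
  n <- nrow(x)
  wlen <- round(window_sec * rate)
  wlen <- min(wlen, n)
  hop <- max(1, round(wlen * (1 - overlap_frac)))
  starts <- seq(1, max(1, n - wlen + 1), by = hop)
  if (starts[length(starts)] + wlen - 1 < n) {
    starts <- c(starts, n - wlen + 1)
  }
  win <- hann_periodic(wlen)
  out <- numeric(n)
  wsum <- numeric(n)
  prev_axis <- NULL
  for (s0 in starts) {
    idx <- s0:(s0 + wlen - 1)
    seg <- x[idx, , drop = FALSE]
    cv <- crossprod(seg) / nrow(seg)
    axis <- tryCatch({
      ev <- eigen(cv, symmetric = TRUE)
      if (ev$values[1] < 1e-18 * max(1, sum(diag(cv)))) stop("rank deficient")
      ev$vectors[, 1]
    }, error = function(e) prev_axis)
    if (is.null(axis)) axis <- c(1, 0, 0)
    # Sign continuity: align with the previous window's axis; the first
    # window's sign makes its largest-magnitude component positive.
    if (is.null(prev_axis)) {
      if (axis[which.max(abs(axis))] < 0) axis <- -axis
    } else if (sum(axis * prev_axis) < 0) {
      axis <- -axis
    }
    prev_axis <- axis
    proj <- as.numeric(seg %*% axis)
    proj <- proj - mean(proj)
    out[idx] <- out[idx] + win * proj
    wsum[idx] <- wsum[idx] + win
  }
  out / pmax(wsum, 1e-8)
}

extract_resp_common <- function(acc, cfg, in_plane) {
  stopifnot(inherits(acc, "accel_trace"))
  if (nrow(acc$samples) < acc$rate * 60) {
    stop("need at least 60 s of accelerometry for respiration extraction")
  }
  filled <- fill_gaps(acc$samples, acc$rate)
  x <- filled$x
  # Remove the quasi-static (gravity + posture) component first: a
  # complementary zero-phase high-pass that takes out the ~1 g offset
  # exactly, so the band-pass sees a small zero-mean residual and leaves
  # no large edge transients.
  lp <- signal::butter(2, cfg$gravity_lp_hz / (acc$rate / 2), type = "low")
  quasi <- filt_cols(x, lp, acc$rate, 4 / cfg$gravity_lp_hz)
  bp <- signal::butter(3, c(cfg$band_low_hz, cfg$band_high_hz) / (acc$rate / 2),
                       type = "pass")
  xb <- filt_cols(x - quasi, bp, acc$rate, 4 / cfg$band_low_hz)
  if (in_plane) {
    nrm <- sqrt(rowSums(quasi^2))
    if (all(nrm < 1e-9)) stop("degenerate gravity: all-zero acceleration trace")
    g <- quasi / pmax(nrm, 1e-12)
    xb <- xb - g * rowSums(xb * g)    # remove gravity-parallel component
  }
  y <- principal_axis_ola(xb, acc$rate, cfg$window_sec, cfg$overlap_frac)
  y <- resample_rational(y, cfg$out_rate_num, cfg$out_rate_den * acc$rate)
  flags <- if (filled$long_gap) "long_gap_zero_filled" else character(0)
  out <- resp_signal(y, rate = cfg$out_rate_num / cfg$out_rate_den,
                     start_time = acc$start_time)
  out$quality_flags <- flags
  out
}

#' Extract respiration: gravity-plane baseline
#'
#' Band-passes the acceleration, removes the component parallel to the
#' local gravity estimate, and projects each window onto the first
#' principal axis of the in-plane covariance (sign-aligned, Hann
#' overlap-added), then resamples to the model's respiratory grid.
#'
#' @param acc [accel_trace].
#' @param cfg [extraction_config] (mode is forced to `GRAVITY_PLANE`).
#' @return [resp_signal].
#' @export
extract_resp_gravity_plane <- function(acc, cfg = extraction_config(mode = "GRAVITY_PLANE")) {
  extract_resp_common(acc, cfg, in_plane = TRUE)
}

#' Extract respiration: orientation-robust variant
#'
#' Like the gravity-plane method but without the geometric projection:
#' the quasi-static gravity component is removed by the band-pass high
#' edge alone and the principal axis is found in the full 3-D windowed
#' covariance, so chest-wall motion is recovered regardless of its angle
#' to gravity (including supine postures where respiration is nearly
#' gravity-parallel).
#'
#' @param acc [accel_trace].
#' @param cfg [extraction_config].
#' @return [resp_signal].
#' @export
extract_resp_orientation_robust <- function(acc, cfg = extraction_config()) {
  extract_resp_common(acc, cfg, in_plane = FALSE)
}

#' Extract respiration according to `cfg$mode`
#' @param acc [accel_trace].
#' @param cfg [extraction_config].
#' @return [resp_signal].
#' @export
extract_resp <- function(acc, cfg = extraction_config()) {
  if (cfg$mode == "GRAVITY_PLANE") extract_resp_gravity_plane(acc, cfg)
  else extract_resp_orientation_robust(acc, cfg)
}

#' Breathing-rate series from a respiratory waveform
#'
#' Dominant-frequency estimate per window, clipped to the respiratory
#' band and expressed in breaths/min. Flat windows yield `NA`.
#'
#' @param resp [resp_signal].
#' @param window_sec Window length, s (>= 3 breath periods at the band's
#'   low edge).
#' @param band Length-2 numeric band in Hz.
#' @return data.frame with columns `t_sec` (window center) and `brpm`.
#' @export
estimate_breath_rate <- function(resp, window_sec = 60,
                                 band = c(0.08, 0.8)) {
  stopifnot(inherits(resp, "resp_signal"))
  if (window_sec < 3 / band[1]) {
    stop("window must cover at least 3 breath periods at the band's low edge")
  }
  wlen <- round(window_sec * resp$rate)
  n <- length(resp$samples)
  starts <- seq(1, max(1, n - wlen + 1), by = wlen)
  rows <- lapply(starts, function(s0) {
    idx <- s0:min(n, s0 + wlen - 1)
    f <- dominant_frequency(resp$samples[idx], resp$rate, band)
    data.frame(t_sec = resp$start_time + (mean(idx) - 1) / resp$rate,
               brpm = if (is.na(f)) NA_real_ else
                 min(band[2], max(band[1], f)) * 60)
  })
  do.call(rbind, rows)
}
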