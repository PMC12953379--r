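# Shared numeric helpers: seeding, resampling, spectra.

#' Derive a reproducible child seed
#'
#' Mixes a base seed with a stream of integer tags (participant index,
#' night index, ...) through a multiplicative-congruential hash so that
#' every simulated object gets an independent, reproducible RNG stream.
#' Results stay below 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param ... Additional integer tags.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in tags) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rational-ratio polyphase resampling
#'
#' Resamples a signal by the exact rational factor `p/q` (after reduction)
#' with `signal::resample`, so that fixed-duration recordings land on
#' bit-reproducible sample grids (e.g. 125 Hz -> 307,200/36,000 Hz via
#' 128/1875).
#'
#' @param x Numeric vector.
#' @param p,q Integers; the output rate is `p/q` times the input rate.
#' @return Numeric vector of length `ceiling(length(x) * p / q)`.
#' @export
resample_rational <- function(x, p, q) {
  g <- gcd_int(p, q)
  p <- p / g
  q <- q / g
  if (p == q) return(x)
  as.numeric(signal::resample(x, p, q))
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Dominant frequency of a signal by FFT
#'
#' Returns the frequency (Hz) of the largest spectral magnitude within
#' `band`, after mean removal and Hann windowing.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param band Length-2 numeric, search band in Hz.
#' @return Frequency in Hz, or `NA_real_` if the signal is flat.
#' @export
dominant_frequency <- function(x, rate, band = c(0.05, rate / 2)) {
  x <- x - mean(x)
  if (all(abs(x) < 1e-12)) return(NA_real_)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
  X <- abs(stats::fft(x * w))[seq_len(floor(n / 2) + 1)]
  f <- (seq_along(X) - 1) * rate / n
  sel <- f >= band[1] & f <= band[2]
  if (!any(sel)) return(NA_real_)
  f[sel][which.max(X[sel])]
}

# Hann window (periodic form: 50%-overlapped copies sum to a constant).
hann_periodic <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

# Fraction of spectral power inside a band.
band_power_fraction <- function(x, rate, band) {
  x <- x - mean(x)
  n <- length(x)
  X <- abs(stats::fft(x))[seq_len(floor(n / 2) + 1)]^2
  f <- (seq_along(X) - 1) * rate / n
  sum(X[f >= band[1] & f <= band[2]]) / sum(X)
}
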