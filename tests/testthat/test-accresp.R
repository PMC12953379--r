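# ACC-RESP derivation: gravity tracking, principal-axis projection,
# mode contrast, rate estimation.

make_trace <- function(dur = 400, fs = 125, resp = NULL, gravity = c(0, 0, 1),
                       noise = 0.002, seed = 1) {
  set.seed(seed)
  n <- dur * fs
  acc <- matrix(stats::rnorm(3 * n, sd = noise), n, 3)
  acc <- acc + matrix(gravity, n, 3, byrow = TRUE)
  if (!is.null(resp)) acc <- acc + resp$wave %o% resp$axis
  accel_trace(acc, rate = fs)
}

sine_wave <- function(freq, dur = 400, fs = 125, amp = 0.01) {
  amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs)
}

test_that("gravity estimation: constant input, ripple attenuation, step response", {
  fs <- 125
  tr <- make_trace(dur = 120, noise = 0)
  g <- estimate_gravity(tr)
  expect_true(all(abs(g - matrix(c(0, 0, 1), nrow(g), 3, byrow = TRUE)) < 1e-6))

  # 0.3 Hz, 0.05 g ripple on x: attenuated to < 3 degrees off vertical
  # (second-order low-pass at 0.04 Hz, applied forward-backward, leaves
  # (0.04/0.3)^4 ~ 3e-4 of the ripple)
  tr2 <- make_trace(dur = 120, noise = 0)
  tr2$samples[, 1] <- tr2$samples[, 1] + sine_wave(0.3, 120, amp = 0.05)
  g2 <- estimate_gravity(tr2)
  ang <- acos(pmin(1, g2[, 3])) * 180 / pi
  expect_lt(max(ang), 3)

  # step rotation supine -> left lateral: converges within 3 / cutoff s
  dur <- 400
  n <- dur * fs
  acc <- matrix(0, n, 3)
  half <- n / 2
  acc[1:half, 3] <- 1
  acc[(half + 1):n, 1] <- 1
  g3 <- estimate_gravity(accel_trace(acc, fs))
  cfg <- extraction_config()
  settle <- half + ceiling(3 / cfg$gravity_lp_hz * fs)
  late <- g3[settle:n, ]
  ang3 <- acos(pmin(1, late[, 1])) * 180 / pi
  expect_lt(max(ang3), 10)

  expect_error(estimate_gravity(accel_trace(matrix(0, 125 * 60, 3), fs)),
               "degenerate")
})

test_that("gravity-plane mode is blind to gravity-parallel respiration", {
  wave <- sine_wave(0.20)
  tr <- make_trace(resp = list(wave = wave, axis = c(0, 0, 1)))
  out <- extract_resp_gravity_plane(tr)
  # band-passed input motion variance on the respiration axis
  bp <- signal::butter(3, c(0.08, 0.8) / (125 / 2), "pass")
  ref_var <- stats::var(as.numeric(signal::filtfilt(bp, tr$samples[, 3])))
  expect_lt(stats::var(out$samples) / ref_var, 0.05)
})

test_that("gravity-plane mode recovers in-plane respiration at the true rate", {
  wave <- sine_wave(0.25)
  tr <- make_trace(resp = list(wave = wave, axis = c(1, 0, 0)))
  out <- extract_resp_gravity_plane(tr)
  expect_equal(dominant_frequency(out$samples, out$rate, c(0.08, 0.8)), 0.25,
               tolerance = 0.02 / 0.25)
})

test_that("orientation-robust mode recovers gravity-parallel respiration", {
  wave <- sine_wave(0.20)
  tr <- make_trace(resp = list(wave = wave, axis = c(0, 0, 1)))
  out <- extract_resp_orientation_robust(tr)
  expect_equal(dominant_frequency(out$samples, out$rate, c(0.08, 0.8)), 0.20,
               tolerance = 0.02 / 0.20)
})

test_that("orientation-robust output is equivariant to fixed rotations", {
  wave <- sine_wave(0.25)
  tr <- make_trace(resp = list(wave = wave, axis = c(1, 0, 0)))
  a1 <- 0.7
  a2 <- 0.4
  R <- rbind(c(cos(a1), -sin(a1), 0), c(sin(a1), cos(a1), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(a2), -sin(a2)), c(0, sin(a2), cos(a2)))
  out1 <- extract_resp_orientation_robust(tr)
  out2 <- extract_resp_orientation_robust(
    accel_trace(tr$samples %*% t(R), tr$rate))
  expect_gt(abs(stats::cor(out1$samples, out2$samples)), 0.99)
})

test_that("zero-motion input yields (near-)zero output", {
  tr <- make_trace(dur = 120, noise = 0)
  out <- extract_resp_orientation_robust(tr)
  expect_lt(sqrt(mean(out$samples^2)), 1e-6)
})

test_that("white noise gains no breath-band power from the projection", {
  set.seed(8)
  n <- 300 * 125
  tr <- accel_trace(matrix(stats::rnorm(3 * n, sd = 0.01), n, 3), 125)
  out <- extract_resp_orientation_robust(tr)
  # filter-only reference: band-pass one axis, same band fraction measure
  bp <- signal::butter(3, c(0.08, 0.8) / (125 / 2), "pass")
  ref <- as.numeric(signal::filtfilt(bp, tr$samples[, 1]))
  frac_out <- band_power_fraction(out$samples[-(1:50)], out$rate, c(0.08, 0.8))
  frac_ref <- band_power_fraction(ref, 125, c(0.08, 0.8))
  expect_lt(frac_out, frac_ref * 1.1)
})

test_that("output length and amplitude equivariance", {
  wave <- sine_wave(0.25, dur = 300)
  tr <- make_trace(dur = 300, resp = list(wave = wave, axis = c(1, 0, 0)))
  out <- extract_resp_orientation_robust(tr)
  expect_lte(abs(length(out$samples) - round(300 * 307200 / 36000)), 1)

  tr3 <- accel_trace(tr$samples * 3, tr$rate)
  out3 <- extract_resp_orientation_robust(tr3)
  expect_equal(stats::sd(out3$samples) / stats::sd(out$samples), 3,
               tolerance = 1e-3)
  expect_gt(abs(stats::cor(out$samples, out3$samples)), 0.9999)
})

test_that("orientation-robust dominates gravity-plane near gravity-parallel axes", {
  wave <- sine_wave(0.23, dur = 300)
  truth <- resample_rational(wave, 307200, 36000 * 125)
  for (theta_deg in c(0, 10, 20)) {
    th <- theta_deg * pi / 180
    axis <- c(sin(th), 0, cos(th))
    tr <- make_trace(dur = 300, resp = list(wave = wave, axis = axis),
                     seed = 100 + theta_deg)
    c_rob <- abs(stats::cor(extract_resp_orientation_robust(tr)$samples, truth))
    c_pln <- abs(stats::cor(extract_resp_gravity_plane(tr)$samples, truth))
    expect_gt(c_rob, c_pln)
    expect_gt(c_rob, 0.95)
  }
})

test_that("breath-rate estimation: pure tones, two-tone dominance, flat signal", {
  r <- resp_signal(sin(2 * pi * 0.25 * (0:5119) / RESP_MODEL_HZ))
  br <- estimate_breath_rate(r)
  expect_true(all(abs(br$brpm - 15) < 0.5))

  two <- sin(2 * pi * 0.2 * (0:5119) / RESP_MODEL_HZ) +
    0.3 * sin(2 * pi * 0.4 * (0:5119) / RESP_MODEL_HZ)
  br2 <- estimate_breath_rate(resp_signal(two))
  expect_true(all(abs(br2$brpm - 12) < 0.5))

  br3 <- estimate_breath_rate(resp_signal(numeric(5120)))
  expect_true(all(is.na(br3$brpm)))

  expect_error(estimate_breath_rate(r, window_sec = 10), "3 breath periods")
})

test_that("deep-sleep breathing rate survives the full derivation chain", {
  rec <- generate_night(hypnogram(rep("N3", 40)), quiet_physio(), seed = 5)
  r <- extract_resp_orientation_robust(rec$accel)
  br <- estimate_breath_rate(r)
  expect_equal(median(br$brpm, na.rm = TRUE), 13, tolerance = 0.5 / 13)
})

test_that("interior gaps are interpolated; long gaps zero-filled and flagged", {
  wave <- sine_wave(0.25, dur = 120)
  tr <- make_trace(dur = 120, resp = list(wave = wave, axis = c(1, 0, 0)))
  tr$samples[1000:1100, ] <- NA          # 0.8 s gap: interpolated
  out <- extract_resp_orientation_robust(tr)
  expect_false(anyNA(out$samples))
  expect_length(out$quality_flags, 0)

  tr$samples[5000:(5000 + 10 * 125), ] <- NA   # 10 s gap: zero-filled
  out2 <- extract_resp_orientation_robust(tr)
  expect_true("long_gap_zero_filled" %in% out2$quality_flags)
})
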