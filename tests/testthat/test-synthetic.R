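# Synthetic cohort simulator: hypnogram chain, waveforms, cohorts.

test_that("hypnogram generation: epoch count, determinism, parameter errors", {
  hp <- hypnogram_params()
  expect_length(generate_hypnogram(hp, 10, seed = 1), 1200)
  expect_length(generate_hypnogram(hp, 8, seed = 1), 960)
  expect_length(generate_hypnogram(hp, 0.51, seed = 1), ceiling(0.51 * 120))

  expect_identical(unclass(generate_hypnogram(hp, 8, seed = 5)),
                   unclass(generate_hypnogram(hp, 8, seed = 5)))
  expect_false(identical(unclass(generate_hypnogram(hp, 8, seed = 5)),
                         unclass(generate_hypnogram(hp, 8, seed = 6))))

  bad <- default_transition_matrix()
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(hypnogram_params(transition = bad), "stochastic")
  expect_error(generate_hypnogram(hp, 0), "duration_hr")
  expect_error(generate_hypnogram(hp, 11), "duration_hr")
})

test_that("identity transition matrix is absorbing: all-wake half hour", {
  hp <- hypnogram_params(transition = diag(4), sol_min = 0,
                         rem_gate_gain = 1, rem_offgain = 1)
  # with sol_min = 0 the chain starts by leaving wake; force absorbing
  # dynamics by starting from the latency phase instead
  hp2 <- hypnogram_params(transition = diag(4), sol_min = 1e9)
  h <- generate_hypnogram(hp2, 0.5, seed = 3)
  expect_length(h, 60)
  expect_true(all(h == "WAKE"))
})

test_that("long-run stage fractions match the chain's stationary distribution", {
  hp <- hypnogram_params()
  # oracle: eigen-decomposition of the transposed transition matrix
  e <- eigen(t(hp$transition))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_oracle <- v / sum(v)

  fr <- matrix(0, 200, 4)
  for (i in 1:200) {
    h <- generate_hypnogram(hp, 8, seed = i)
    fr[i, ] <- tabulate(stage_index(h), 4) / length(h)
  }
  expect_true(all(abs(colMeans(fr) - pi_oracle) < 0.05))
})

test_that("sleep-onset latency matches its target and REM cycles are expressed", {
  hp <- hypnogram_params()
  sols <- vapply(1:150, function(i) {
    h <- generate_hypnogram(hp, 8, seed = 3000 + i)
    w <- which(h != "WAKE")[1]
    (w - 1) * 0.5
  }, numeric(1))
  expect_equal(mean(sols), hp$sol_min, tolerance = 0.15)

  # every night of >= 3 h expresses at least one REM bout
  for (i in 1:20) {
    expect_true(any(generate_hypnogram(hp, 4, seed = 100 + i) == "REM"))
  }
})

test_that("generated ECG carries the stage's heart rate (peak-detection oracle)", {
  phys <- quiet_physio()
  rec <- generate_night(hypnogram(rep("N3", 40)), phys, seed = 3)
  beats <- oracle_detect_beats(rec$ecg)
  hr <- length(beats) / (length(rec$ecg) / 125) * 60
  expect_equal(hr, phys$hr_by_stage[["N3"]], tolerance = 1 / 55)

  rec_w <- generate_night(hypnogram(rep("WAKE", 40)), quiet_physio(),
                          seed = 4)
  hr_w <- length(oracle_detect_beats(rec_w$ecg)) / (length(rec_w$ecg) / 125) * 60
  expect_equal(hr_w, 65, tolerance = 1 / 65)
})

test_that("accelerometer: stable posture, respiratory spectral peak, alignment", {
  phys <- quiet_physio()
  rec <- generate_night(hypnogram(rep("N1N2", 40)), phys, seed = 5)
  expect_equal(nrow(rec$accel$samples), length(rec$hypnogram) * 30 * 125)
  expect_equal(length(rec$ecg), nrow(rec$accel$samples))

  # posture_change_rate = 0: gravity direction constant (drift < 1 degree)
  g <- estimate_gravity(rec$accel)
  gm <- colMeans(g)
  gm <- gm / sqrt(sum(gm^2))
  ang <- acos(pmin(1, g %*% gm)) * 180 / pi
  expect_lt(max(ang), 1)

  # N1N2 at 15 breaths/min: band-passed projection peaks at 0.25 Hz
  r <- extract_resp_orientation_robust(rec$accel)
  expect_equal(dominant_frequency(r$samples, r$rate, c(0.08, 0.8)), 0.25,
               tolerance = 0.02 / 0.25)

  # reproducibility
  rec2 <- generate_night(hypnogram(rep("N1N2", 40)), phys, seed = 5)
  expect_identical(rec$ecg, rec2$ecg)
  expect_identical(rec$accel$samples, rec2$accel$samples)
})

test_that("cohort generation: counting, TIB restriction, night labels", {
  plan <- cohort_plan(n_participants = 13, seed = 11)
  cohort <- generate_cohort(plan, waveforms = FALSE)
  expect_length(cohort, 117)
  pids <- vapply(cohort, function(r) r$participant_id, character(1))
  expect_length(unique(pids), 13)
  labels <- vapply(cohort, function(r) r$night_label, character(1))
  expect_setequal(unique(labels), c("B1", paste0("I", 1:7), "F1"))
  # each participant has each label exactly once
  expect_true(all(table(pids, labels) == 1))
})

test_that("injected time-in-bed restriction is recovered from the records", {
  plan <- cohort_plan(n_participants = 12, srt_tib_restriction_min = 120,
                      seed = 21)
  cohort <- generate_cohort(plan, waveforms = FALSE)
  tib <- vapply(cohort, function(r) sleep_metrics(r$hypnogram)$tib_min,
                numeric(1))
  lbl <- vapply(cohort, function(r) r$night_label, character(1))
  drop <- mean(tib[lbl == "B1"]) - mean(tib[lbl == "I1"])
  expect_equal(drop, 120, tolerance = 10 / 120)
})

test_that("injected %N3 trend is recovered by least squares on cohort means", {
  # cohort sized so the slope's sampling error (~0.13 pp/night) is well
  # inside the +-0.3 recovery tolerance
  plan <- cohort_plan(n_participants = 100, n3_trend_per_night = -1.0,
                      srt_tib_restriction_min = 0, seed = 31)
  cohort <- generate_cohort(plan, waveforms = FALSE)
  pct <- vapply(cohort, function(r) sleep_metrics(r$hypnogram)$pct_n3,
                numeric(1))
  lbl <- vapply(cohort, function(r) r$night_label, character(1))
  k <- as.integer(sub("I", "", lbl[grepl("^I", lbl)]))
  means <- tapply(pct[grepl("^I", lbl)], k, mean)
  slope <- unname(stats::coef(stats::lm(means ~ as.numeric(names(means))))[2])
  expect_equal(slope, -1.0, tolerance = 0.3 / 1.0)
})
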