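# Synthetic cohort simulator: cardiorespiratory waveforms and cohorts.

#' Stage-dependent physiology parameters for the simulator
#'
#' Encodes the autonomic coupling the staging model exploits: per-stage
#' mean heart rate, beat-to-beat variability, respiratory rate and
#' irregularity, plus respiratory-sinus-arrhythmia (RSA) coupling of the
#' RR series to the respiration phase. The accelerometer model is a
#' piecewise-constant gravity unit vector (posture) plus sinusoid-like
#' chest-wall displacement along a fixed body axis, motion bursts during
#' wake, and white sensor noise. Defaults are editable synthetic
#' conventions (see also `inst/extdata/default_physiology.yaml`), not
#' values measured from any clinical cohort.
#'
#' @param hr_by_stage Mean heart rate per stage, beats/min
#'   (WAKE/N1N2/N3/REM).
#' @param hrv_sd_by_stage Beat-to-beat RR standard deviation per stage, ms.
#' @param rsa_amp_by_stage RSA amplitude of the RR series per stage, s.
#' @param resp_rate_by_stage Respiratory rate per stage, breaths/min.
#' @param resp_irregularity_by_stage Relative low-frequency wobble of the
#'   instantaneous respiratory rate (unitless; REM highest).
#' @param resp_axis Unit 3-vector: direction of chest-wall respiratory
#'   displacement in the device frame.
#' @param resp_amp_g Respiratory displacement amplitude, g.
#' @param posture_change_rate Posture-change events per hour.
#' @param wake_motion_burst_rate Motion bursts per hour of wake.
#' @param accel_noise_g Accelerometer white-noise SD, g.
#' @param ecg_noise Additive ECG noise SD (arbitrary ECG units).
#' @param seed Integer RNG seed.
#' @return Object of class `physio_params`.
#' @export
physio_params <- function(hr_by_stage = c(WAKE = 65, N1N2 = 60, N3 = 55, REM = 62),
                          hrv_sd_by_stage = c(WAKE = 60, N1N2 = 40, N3 = 25, REM = 70),
                          rsa_amp_by_stage = c(WAKE = 0.010, N1N2 = 0.025,
                                               N3 = 0.035, REM = 0.015),
                          resp_rate_by_stage = c(WAKE = 14, N1N2 = 15, N3 = 13, REM = 16),
                          resp_irregularity_by_stage = c(WAKE = 0.10, N1N2 = 0.05,
                                                         N3 = 0.02, REM = 0.20),
                          resp_axis = c(0.2, 0.1, 0.97),
                          resp_amp_g = 0.010,
                          posture_change_rate = 1.5,
                          wake_motion_burst_rate = 20,
                          accel_noise_g = 0.002,
                          ecg_noise = 0.03,
                          seed = 1L) {
  if (any(hr_by_stage <= 0) || any(resp_rate_by_stage <= 0)) {
    stop("rates must be positive")
  }
  nrm <- sqrt(sum(resp_axis^2))
  if (abs(nrm - 1) > 1e-9) resp_axis <- resp_axis / nrm
  structure(list(hr_by_stage = hr_by_stage,
                 hrv_sd_by_stage = hrv_sd_by_stage,
                 rsa_amp_by_stage = rsa_amp_by_stage,
                 resp_rate_by_stage = resp_rate_by_stage,
                 resp_irregularity_by_stage = resp_irregularity_by_stage,
                 resp_axis = resp_axis, resp_amp_g = resp_amp_g,
                 posture_change_rate = posture_change_rate,
                 wake_motion_burst_rate = wake_motion_burst_rate,
                 accel_noise_g = accel_noise_g, ecg_noise = ecg_noise,
                 seed = as.integer(seed)),
            class = "physio_params")
}

# Canonical gravity directions (device frame) per lying posture.
POSTURE_GRAVITY <- rbind(supine = c(0, 0, 1),
                         left_lateral = c(1, 0, 0),
                         right_lateral = c(-1, 0, 0),
                         prone = c(0, 0, -1))

# ECG beat template at 125 Hz: R-peak with Q/S dips and a T wave.
ecg_beat_template <- function(fs = 125) {
  tt <- seq(-0.10, 0.38, by = 1 / fs)
  qrs <- exp(-0.5 * (tt / 0.012)^2) -
    0.18 * exp(-0.5 * ((tt + 0.035) / 0.015)^2) -
    0.22 * exp(-0.5 * ((tt - 0.035) / 0.015)^2)
  twave <- 0.28 * exp(-0.5 * ((tt - 0.25) / 0.05)^2)
  list(shape = qrs + twave, offsets = round(tt * fs))
}

# Smooth low-frequency unit-variance noise at the waveform rate.
slow_noise <- function(n, fs, tau_sec = 10) {
  n_sec <- max(2, ceiling(n / fs) + 1)
  a <- exp(-1 / tau_sec)
  e <- as.numeric(stats::filter(stats::rnorm(n_sec, sd = sqrt(1 - a^2)),
                                a, method = "recursive"))
  stats::approx(seq_len(n_sec), e, xout = seq_len(n) / fs + 1,
                rule = 2)$y
}

#' Generate one night of synthetic ECG and accelerometry
#'
#' Renders a hypnogram into aligned waveforms at 125 Hz: ECG as a
#' template beat train whose inter-beat intervals follow per-stage
#' Gaussian statistics plus an RSA sinusoid locked to the respiration
#' phase; accelerometry as posture gravity + respiratory displacement
#' along `resp_axis` + wake motion bursts + sensor noise. Epoch k of the
#' hypnogram covers samples `[k*30*125, (k+1)*30*125)` (0-based) of both
#' waveforms.
#'
#' @param hyp [hypnogram].
#' @param phys [physio_params].
#' @param seed Optional seed overriding `phys$seed`.
#' @param participant_id,night_label Metadata attached to the record.
#' @return [night_record] with `truth` carrying the generator's posture
#'   and respiration ground truth.
#' @export
generate_night <- function(hyp, phys, seed = phys$seed,
                           participant_id = "SYN", night_label = NA_character_) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(phys, "physio_params"))
  if (length(hyp) == 0) stop("hypnogram must be non-empty")
  fs <- 125
  n_ep <- length(hyp)
  n <- n_ep * EPOCH_SEC * fs
  dur <- n / fs
  sidx <- stage_index(hyp)
  sidx[is.na(sidx)] <- 1L                    # ARTIFACT/PAD rendered as wake
  stage_smp <- rep(sidx, each = EPOCH_SEC * fs)

  with_seed(seed, {
    ## Respiration phase (shared by the accelerometer and the RSA term)
    f_inst <- phys$resp_rate_by_stage[stage_smp] / 60 *
      (1 + phys$resp_irregularity_by_stage[stage_smp] * slow_noise(n, fs, 8))
    f_inst <- pmax(f_inst, 0.02)
    phase <- 2 * pi * cumsum(f_inst) / fs
    resp_disp <- phys$resp_amp_g * sin(phase)

    ## Posture: piecewise-constant gravity direction, exponential holds
    g_dir <- matrix(0, n, 3)
    post_state <- sample.int(nrow(POSTURE_GRAVITY), 1)
    t0 <- 0
    changes <- numeric(0)
    repeat {
      hold <- if (phys$posture_change_rate > 0) {
        stats::rexp(1, rate = phys$posture_change_rate / 3600)
      } else Inf
      t1 <- min(t0 + hold, dur)
      i0 <- floor(t0 * fs) + 1
      i1 <- max(i0, ceiling(t1 * fs))
      i1 <- min(i1, n)
      g_dir[i0:i1, ] <- matrix(POSTURE_GRAVITY[post_state, ], i1 - i0 + 1, 3,
                               byrow = TRUE)
      if (t1 >= dur) break
      changes <- c(changes, t1)
      post_state <- sample(setdiff(seq_len(nrow(POSTURE_GRAVITY)), post_state), 1)
      t0 <- t1
    }
    # 2-s cross-fade at posture changes, renormalized to unit length
    for (tc in changes) {
      j0 <- max(1, floor((tc - 1) * fs))
      j1 <- min(n, ceiling((tc + 1) * fs))
      if (j1 - j0 < 2) next
      w <- seq(0, 1, length.out = j1 - j0 + 1)
      g_dir[j0:j1, ] <- (1 - w) %o% g_dir[j0, ] + w %o% g_dir[j1, ]
    }
    g_dir <- g_dir / sqrt(pmax(rowSums(g_dir^2), 1e-12))

    ## Accelerometer
    acc <- g_dir + resp_disp %o% phys$resp_axis +
      matrix(stats::rnorm(n * 3, sd = phys$accel_noise_g), n, 3)
    # Motion bursts during wake
    wake_smp <- which(stage_smp == 1L)
    wake_hr <- length(wake_smp) / fs / 3600
    n_burst <- stats::rpois(1, phys$wake_motion_burst_rate * wake_hr)
    if (n_burst > 0 && length(wake_smp) > fs) {
      starts <- sort(sample(wake_smp, n_burst))
      for (b in starts) {
        len <- round(stats::runif(1, 1, 4) * fs)
        j <- b:min(b + len, n)
        env <- sin(pi * seq_along(j) / length(j))^2
        for (ax in 1:3) {
          acc[j, ax] <- acc[j, ax] +
            0.15 * env * as.numeric(stats::filter(stats::rnorm(length(j)),
                                                  rep(1 / 5, 5), sides = 2,
                                                  circular = TRUE))
        }
      }
    }

    ## ECG: beat train with stage-dependent RR statistics + RSA
    max_beats <- ceiling(dur * 4)
    beat_t <- numeric(max_beats)
    nb <- 0L
    t <- stats::runif(1, 0.2, 1.0)
    while (t < dur) {
      i <- min(n, floor(t * fs) + 1)
      s <- stage_smp[i]
      rr <- 60 / phys$hr_by_stage[s] +
        stats::rnorm(1, sd = phys$hrv_sd_by_stage[s] / 1000) +
        phys$rsa_amp_by_stage[s] * sin(phase[i])
      rr <- min(2, max(0.35, rr))
      nb <- nb + 1L
      beat_t[nb] <- t
      t <- t + rr
    }
    beat_t <- beat_t[seq_len(nb)]
    ecg <- stats::rnorm(n, sd = phys$ecg_noise)
    tmpl <- ecg_beat_template(fs)
    bidx <- round(beat_t * fs) + 1L
    for (k in seq_along(tmpl$offsets)) {
      j <- bidx + tmpl$offsets[k]
      ok <- j >= 1 & j <= n
      ecg[j[ok]] <- ecg[j[ok]] + tmpl$shape[k]
    }

    night_record(participant_id = participant_id, night_label = night_label,
                 hypnogram = hyp, ecg = ecg, ecg_rate = fs,
                 accel = accel_trace(acc, rate = fs),
                 truth = list(beat_times = beat_t,
                              posture_changes = changes,
                              resp_wave = resp_disp,
                              resp_wave_rate = fs))
  })
}

#' Longitudinal cohort plan
#'
#' Describes a sleep-restriction protocol cohort: one baseline night
#' (`B1`), seven intervention nights (`I1`..`I7`) with restricted time in
#' bed, and one follow-up night (`F1`). Time-in-bed restriction is
#' maximal on I1 and relaxes linearly so that it has fully recovered by
#' F1; the deep-sleep share drifts by `n3_trend_per_night` percentage
#' points per intervention night.
#'
#' @param n_participants Number of participants (>= 3).
#' @param nights Character vector of night labels per participant.
#' @param srt_tib_restriction_min Minutes removed from time in bed on I1.
#' @param n3_trend_per_night Drift of %N3 (of sleep) across I1..I7,
#'   percentage points per night.
#' @param tib_base_min Baseline time in bed, minutes.
#' @param tib_jitter_sd_min Night-to-night SD of time in bed, minutes.
#' @param seed Integer RNG seed.
#' @return Object of class `cohort_plan`.
#' @export
cohort_plan <- function(n_participants = 13,
                        nights = c("B1", paste0("I", 1:7), "F1"),
                        srt_tib_restriction_min = 120,
                        n3_trend_per_night = -1.0,
                        tib_base_min = 480,
                        tib_jitter_sd_min = 10,
                        seed = 1L) {
  if (n_participants < 3) stop("n_participants must be >= 3")
  if (anyDuplicated(nights)) stop("night labels must be unique per participant")
  ok <- nights %in% c("B1", paste0("I", 1:7), "F1")
  if (!all(ok)) stop("night labels must be drawn from B1, I1..I7, F1")
  structure(list(n_participants = as.integer(n_participants), nights = nights,
                 srt_tib_restriction_min = srt_tib_restriction_min,
                 n3_trend_per_night = n3_trend_per_night,
                 tib_base_min = tib_base_min,
                 tib_jitter_sd_min = tib_jitter_sd_min,
                 seed = as.integer(seed)),
            class = "cohort_plan")
}

# Time-in-bed restriction (minutes) for a night label under a plan.
tib_restriction_min <- function(label, plan) {
  if (grepl("^I[1-7]$", label)) {
    k <- as.integer(sub("I", "", label))
    plan$srt_tib_restriction_min * (8 - k) / 7
  } else 0
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws one [night_record] per participant-night under `plan`. The %N3
#' drift is injected by calibrating a per-night gain on N3 entry
#' probabilities against the chain's stationary distribution
#' ([calibrate_n3_gain()]); time in bed is shortened per the restriction
#' schedule. With `waveforms = FALSE` only hypnograms are rendered
#' (sufficient for sleep-architecture analyses and far cheaper).
#'
#' @param plan [cohort_plan].
#' @param hparams [hypnogram_params].
#' @param phys [physio_params].
#' @param waveforms Render ECG/accelerometry (`TRUE`) or labels only.
#' @param transform Function applied to each [night_record] as it is
#'   generated (before storage). Supplying the downstream pipeline here
#'   (e.g. respiration extraction + model gridding) keeps peak memory at
#'   one night's waveforms instead of the whole cohort's.
#' @return List of [night_record] (class `night_cohort`), or of
#'   `transform`'s outputs.
#' @export
generate_cohort <- function(plan, hparams = hypnogram_params(),
                            phys = physio_params(), waveforms = TRUE,
                            transform = identity) {
  stopifnot(inherits(plan, "cohort_plan"))
  base_frac <- {
    pi0 <- stationary_distribution(hparams$transition)
    pi0[3] / sum(pi0[2:4])
  }
  # The realized %N3 of a finite, cycle-modulated night responds less
  # than one-for-one to a stationary-calibrated gain (REM pressure and
  # cycle gating push back). Estimate the realized-vs-stationary
  # response ratio once by Monte Carlo and widen the stationary targets
  # accordingly, so injected trends come out at face value.
  rho <- 1
  has_trend <- plan$n3_trend_per_night != 0 && any(grepl("^I[1-7]$", plan$nights))
  if (has_trend) {
    mc_share <- function(gain, tag) {
      mean(vapply(seq_len(200), function(i) {
        h <- generate_hypnogram(hparams, 8, n3_gain = gain,
                                seed = derive_seed(plan$seed, tag, i))
        st <- as.character(h)
        ns <- sum(st %in% c("N1N2", "N3", "REM"))
        if (ns == 0) return(NA_real_)
        sum(st == "N3") / ns
      }, numeric(1)), na.rm = TRUE)
    }
    d7 <- plan$n3_trend_per_night * 6 / 100
    s_probe <- min(0.9, max(0.02, base_frac + d7))
    g_probe <- calibrate_n3_gain(hparams$transition, s_probe)
    r1 <- mc_share(1, 555L)
    r2 <- mc_share(g_probe, 556L)
    if (abs(s_probe - base_frac) > 1e-9) {
      rho <- (r2 - r1) / (s_probe - base_frac)
      rho <- min(2, max(0.25, rho))
    }
  }
  # Per-night N3 gains (shared across participants)
  gains <- vapply(plan$nights, function(lb) {
    if (grepl("^I[1-7]$", lb)) {
      k <- as.integer(sub("I", "", lb))
      tgt <- base_frac + plan$n3_trend_per_night * (k - 1) / 100 / rho
      tgt <- min(0.9, max(0.02, tgt))
      calibrate_n3_gain(hparams$transition, tgt)
    } else 1
  }, numeric(1))

  records <- list()
  for (p in seq_len(plan$n_participants)) {
    pid <- sprintf("P%02d", p)
    for (j in seq_along(plan$nights)) {
      lb <- plan$nights[j]
      sd_night <- derive_seed(plan$seed, p, j)
      tib <- plan$tib_base_min - tib_restriction_min(lb, plan) +
        with_seed(derive_seed(sd_night, 7L),
                  stats::rnorm(1, sd = plan$tib_jitter_sd_min))
      tib <- min(600, max(60, tib))
      dur_hr <- (round(tib * 2) / 2) / 60       # whole epochs
      hyp <- generate_hypnogram(hparams, dur_hr, n3_gain = gains[j],
                                seed = derive_seed(sd_night, 11L))
      rec <- if (waveforms) {
        r <- generate_night(hyp, phys, seed = derive_seed(sd_night, 13L),
                            participant_id = pid, night_label = lb)
        r$truth$resp_wave <- NULL    # drop bulky ground truth at cohort scale
        r
      } else {
        night_record(participant_id = pid, night_label = lb, hypnogram = hyp)
      }
      records[[length(records) + 1L]] <- transform(rec)
    }
  }
  structure(records, class = "night_cohort")
}

#' Load the default physiology parameter file
#'
#' Reads the editable YAML parameter file shipped in
#' `inst/extdata/default_physiology.yaml` (or a user-supplied file with
#' the same keys) into a [physio_params] object.
#'
#' @param path YAML file; defaults to the packaged parameter file.
#' @param seed RNG seed attached to the parameters.
#' @return [physio_params].
#' @export
load_physio_params <- function(path = system.file("extdata",
                                                  "default_physiology.yaml",
                                                  package = "cardiosleep"),
                               seed = 1L) {
  y <- yaml::read_yaml(path)
  named <- function(v) stats::setNames(as.numeric(v), SLEEP_STAGES)
  physio_params(hr_by_stage = named(y$hr_by_stage),
                hrv_sd_by_stage = named(y$hrv_sd_by_stage),
                rsa_amp_by_stage = named(y$rsa_amp_by_stage),
                resp_rate_by_stage = named(y$resp_rate_by_stage),
                resp_irregularity_by_stage = named(y$resp_irregularity_by_stage),
                resp_axis = as.numeric(y$resp_axis),
                resp_amp_g = y$resp_amp_g,
                posture_change_rate = y$posture_change_rate,
                wake_motion_burst_rate = y$wake_motion_burst_rate,
                accel_noise_g = y$accel_noise_g,
                ecg_noise = y$ecg_noise, seed = seed)
}

#' Alternative autonomic-coupling convention for transfer experiments
#'
#' A second synthetic "population" whose stage-to-physiology mapping is
#' genuinely reordered relative to [physio_params()] — REM heart rate
#' near wake levels with a compressed light/deep gap, beat-to-beat
#' variability highest in light sleep, respiratory-sinus-arrhythmia
#' strongest in REM, respiratory rates reordered, and a rotated
#' respiratory axis. A model trained under the default convention
#' systematically degrades here, creating the domain gap that
#' transfer-learning experiments adapt across (the within-cohort
#' structure remains fully learnable).
#'
#' @param ... Overrides passed to [physio_params()].
#' @return [physio_params].
#' @export
shifted_physio_params <- function(...) {
  physio_params(
    hr_by_stage = c(WAKE = 70, N1N2 = 62, N3 = 59, REM = 69),
    hrv_sd_by_stage = c(WAKE = 45, N1N2 = 55, N3 = 35, REM = 50),
    rsa_amp_by_stage = c(WAKE = 0.010, N1N2 = 0.015, N3 = 0.015, REM = 0.030),
    resp_rate_by_stage = c(WAKE = 17, N1N2 = 13, N3 = 15, REM = 12),
    resp_irregularity_by_stage = c(WAKE = 0.05, N1N2 = 0.10, N3 = 0.03,
                                   REM = 0.12),
    resp_axis = c(0.7, 0.2, 0.69),
    ...)
}
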