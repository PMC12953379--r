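# Synthetic cohort simulator: hypnogram chain with sleep-cycle structure.

#' Parameters of the synthetic hypnogram generator
#'
#' Sleep-stage sequences are drawn from a first-order Markov chain over
#' \{WAKE, N1N2, N3, REM\} on the 30-s epoch grid, with three structural
#' modulations layered on top:
#' \itemize{
#'   \item a sleep-onset latency phase: the night starts with a geometric
#'     wake run whose expected length is `sol_min` minutes;
#'   \item an ultradian cycle clock of period `mean_cycle_min`: transitions
#'     into REM are up-weighted in the final quarter of each cycle and
#'     down-weighted elsewhere, with gains chosen to average to one so the
#'     chain's long-run stage fractions still match the base matrix;
#'   \item N3 front-loading: transitions into N3 are scaled by
#'     `exp(-n3_front_loading * (cycle - front_load_center))`, so deep
#'     sleep concentrates in early cycles while the time-averaged gain
#'     stays near one.
#' }
#' The default transition matrix is tuned so the chain's stationary stage
#' fractions approximate the label distribution typical of home-monitored
#' insomnia cohorts scored from a frontal-electrode montage (wake ~12%,
#' N1/N2 ~32%, N3 ~35%, REM ~20%).
#'
#' @param mean_cycle_min Ultradian cycle period, minutes (~90).
#' @param transition Row-stochastic 4 x 4 matrix over WAKE/N1N2/N3/REM.
#' @param sol_min Target mean sleep-onset latency, minutes.
#' @param n3_front_loading Decay rate (per cycle) of N3 entry probability.
#' @param front_load_center Cycle index at which the front-loading gain is
#'   one (centers the decay so it averages out over a typical night).
#' @param rem_gate_gain Multiplier on REM entry during the REM window
#'   (the final `rem_window_frac` of each cycle).
#' @param rem_offgain Multiplier on REM entry outside the REM window.
#' @param rem_window_frac Fraction of each cycle forming the REM window.
#' @param seed Integer RNG seed.
#' @return Object of class `hypnogram_params`.
#' @export
hypnogram_params <- function(mean_cycle_min = 90,
                             transition = default_transition_matrix(),
                             sol_min = 15,
                             n3_front_loading = 0.15,
                             front_load_center = 2,
                             rem_gate_gain = 2.6,
                             rem_offgain = 0.45,
                             rem_window_frac = 0.35,
                             seed = 1L) {
  p <- list(mean_cycle_min = mean_cycle_min, transition = transition,
            sol_min = sol_min, n3_front_loading = n3_front_loading,
            front_load_center = front_load_center,
            rem_gate_gain = rem_gate_gain, rem_offgain = rem_offgain,
            rem_window_frac = rem_window_frac,
            seed = as.integer(seed))
  validate_hypnogram_params(p)
  structure(p, class = "hypnogram_params")
}

#' @rdname hypnogram_params
#' @export
default_transition_matrix <- function() {
  P <- rbind(
    WAKE = c(0.8910, 0.1040, 0.0020, 0.0030),
    N1N2 = c(0.0243, 0.9027, 0.0438, 0.0292),
    N3   = c(0.0045, 0.0363, 0.9547, 0.0045),
    REM  = c(0.0174, 0.0349, 0.0058, 0.9419))
  colnames(P) <- SLEEP_STAGES
  P
}

validate_hypnogram_params <- function(p) {
  P <- p$transition
  if (!is.matrix(P) || any(dim(P) != c(4, 4))) {
    stop("transition must be a 4 x 4 matrix over ",
         paste(SLEEP_STAGES, collapse = "/"))
  }
  if (any(P < 0) || any(P > 1) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("transition matrix is not row-stochastic (rows must sum to 1)")
  }
  if (p$mean_cycle_min <= 0) stop("mean_cycle_min must be positive")
  if (p$n3_front_loading < 0) stop("n3_front_loading must be >= 0")
  invisible(p)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized
#' to sum to one. Used to calibrate per-night deep-sleep targets and as a
#' reference for the simulator's long-run stage fractions.
#'
#' @param P Row-stochastic square matrix.
#' @return Numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

# Scale the "into N3" column of P by `gain`, absorbing the change into the
# diagonal so rows stay stochastic. Used both per-epoch (front-loading)
# and per-night (longitudinal %N3 drift).
scale_n3_entries <- function(P, gain) {
  for (i in seq_len(4)) {
    if (i == 3) next
    P[i, 3] <- P[i, 3] * gain
    P[i, i] <- 1 - sum(P[i, -i])
    if (P[i, i] < 0) {           # extreme gain: renormalize the row
      P[i, i] <- 0
      P[i, ] <- P[i, ] / sum(P[i, ])
    }
  }
  P
}

#' Calibrate the N3 entry gain for a target deep-sleep share
#'
#' Finds the multiplier on "into N3" transition probabilities such that
#' the chain's stationary N3 share of sleep (N3 / (N1N2 + N3 + REM))
#' equals `target_frac`. Used by [generate_cohort()] to inject a
#' prescribed per-night %N3 trend.
#'
#' @param P Base 4 x 4 transition matrix.
#' @param target_frac Target N3 fraction of stationary sleep time (0-1).
#' @return Scalar gain.
#' @export
calibrate_n3_gain <- function(P, target_frac) {
  n3_sleep_frac <- function(g) {
    pi <- stationary_distribution(scale_n3_entries(P, g))
    pi[3] / sum(pi[2:4])
  }
  lo <- 0.02
  hi <- 8
  f_lo <- n3_sleep_frac(lo) - target_frac
  f_hi <- n3_sleep_frac(hi) - target_frac
  if (f_lo > 0) return(lo)
  if (f_hi < 0) return(hi)
  stats::uniroot(function(g) n3_sleep_frac(g) - target_frac,
                 c(lo, hi), tol = 1e-6)$root
}

#' Generate a synthetic hypnogram
#'
#' Simulates one night of 30-s epoch labels: a geometric wake run with
#' expected length `sol_min` minutes, followed by the modulated Markov
#' chain described in [hypnogram_params()].
#'
#' @param params [hypnogram_params].
#' @param duration_hr Night duration in hours (0 < duration_hr <= 10).
#' @param n3_gain Extra multiplier on N3 entry probabilities for this
#'   night (used to inject longitudinal deep-sleep trends); default 1.
#' @param seed Optional seed overriding `params$seed`.
#' @return [hypnogram] of `ceiling(duration_hr * 120)` epochs.
#' @export
generate_hypnogram <- function(params, duration_hr, n3_gain = 1,
                               seed = params$seed) {
  validate_hypnogram_params(params)
  if (!(duration_hr > 0 && duration_hr <= 10)) {
    stop("duration_hr must be in (0, 10]")
  }
  n_ep <- ceiling(duration_hr * 120)
  cycle_ep <- params$mean_cycle_min * 2
  P <- params$transition

  with_seed(seed, {
    stages <- integer(n_ep)
    t <- 1L
    # Sleep-onset latency: geometric wake run, mean 2*sol_min epochs,
    # truncated at 4x its mean (tail truncation biases the mean < 2%).
    if (params$sol_min > 0) {
      p_exit <- min(1, 1 / (2 * params$sol_min))
      sol_cap <- ceiling(8 * params$sol_min)
      while (t <= n_ep && t <= sol_cap && stats::runif(1) >= p_exit) {
        stages[t] <- 1L
        t <- t + 1L
      }
      if (t <= n_ep) {
        stages[t] <- 1L   # last wake epoch before the first transition
        t <- t + 1L
      }
    }
    if (t <= n_ep) {
      # Enter sleep from the wake row (excluding staying awake).
      w <- P[1, 2:4] * c(1, n3_gain, 1)
      stages[t] <- 1L + sample.int(3, 1, prob = w)
      onset <- t
      last_rem <- t
      t <- t + 1L
      while (t <= n_ep) {
        el <- t - onset
        cyc <- floor(el / cycle_ep)
        phase <- (el %% cycle_ep) / cycle_ep
        # REM homeostasis: entry pressure grows once a full cycle has
        # elapsed without REM, so every night expresses the ultradian
        # rhythm rather than occasionally skipping it.
        pressure <- min(2.5, max(1, (t - last_rem) / cycle_ep))
        g_n3 <- n3_gain *
          min(3, max(0.2, exp(-params$n3_front_loading *
                                (cyc - params$front_load_center))))
        g_rem <- pressure *
          if (phase >= 1 - params$rem_window_frac) params$rem_gate_gain else params$rem_offgain
        s <- stages[t - 1L]
        if (s == 4L) last_rem <- t
        row <- P[s, ]
        if (s != 3) row[3] <- row[3] * g_n3
        if (s != 4) row[4] <- row[4] * g_rem
        row[s] <- 0
        row[s] <- max(0, 1 - sum(row))
        stages[t] <- sample.int(4, 1, prob = row)
        t <- t + 1L
      }
    }
    hypnogram(SLEEP_STAGES[stages])
  })
}
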