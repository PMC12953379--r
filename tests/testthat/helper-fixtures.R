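# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Quiet physiology: no posture changes or motion bursts, for oracle tests
# that need a clean single-posture signal.
quiet_physio <- function(...) {
  physio_params(posture_change_rate = 0, wake_motion_burst_rate = 0, ...)
}

# Tiny model configuration for fast structural/gradient tests.
tiny_model_config <- function(...) {
  model_config(n_epochs = 4, ecg_encoder_features = c(4, 4),
               resp_encoder_features = c(4), frames_per_epoch = 2,
               epoch_feature_dim = 8, mixer_heads = 2, mixer_ff_dim = 16,
               seq_dilations = c(1, 2), seq_features = 8, ...)
}

random_model_input <- function(cfg, seed = 1, stages = NULL) {
  set.seed(seed)
  labels <- if (is.null(stages)) {
    hypnogram(sample(SLEEP_STAGES, cfg$n_epochs, replace = TRUE))
  } else hypnogram(stages)
  list(ecg = stats::rnorm(cfg$ecg_len), resp = stats::rnorm(cfg$resp_len),
       labels = labels, loss_mask = is_scoreable(labels),
       participant_id = "TST", night_label = "B1")
}

# Simple independent R-peak detector (test oracle: threshold + local
# maximum + refractory distance).
oracle_detect_beats <- function(ecg, fs = 125, threshold = 0.5,
                                min_dist_sec = 0.35) {
  n <- length(ecg)
  mid <- 2:(n - 1)
  pk <- mid[ecg[mid] > threshold & ecg[mid] >= ecg[mid - 1] &
              ecg[mid] > ecg[mid + 1]]
  if (length(pk) == 0) return(integer(0))
  keep <- pk[c(TRUE, diff(pk) > min_dist_sec * fs)]
  keep
}

# The 2-h training-scale cohort pushed through the full signal pipeline
# (generation -> ACC-RESP extraction -> model grid). Used by the
# learnability and transfer acceptance checks.
learnability_inputs <- function() {
  fixture("learn_inputs", function() {
    plan <- cohort_plan(n_participants = 12,
                        nights = c("B1", "I1", "I2", "I3"),
                        srt_tib_restriction_min = 0, n3_trend_per_night = 0,
                        tib_base_min = 120, tib_jitter_sd_min = 0, seed = 42)
    grid <- grid_for_config(reduced_model_config())
    unclass(generate_cohort(plan, hypnogram_params(), physio_params(),
                            transform = function(rec) {
                              rec$resp <- extract_resp(rec$accel)
                              resample_to_model_grid(rec, grid)
                            }))
  })
}

# A physiologically shifted cohort (different autonomic coupling), for
# the transfer-learning contrast.
shifted_inputs <- function() {
  fixture("shifted_inputs", function() {
    plan <- cohort_plan(n_participants = 6, nights = c("B1", "I1"),
                        srt_tib_restriction_min = 0, n3_trend_per_night = 0,
                        tib_base_min = 120, tib_jitter_sd_min = 0, seed = 77)
    grid <- grid_for_config(reduced_model_config())
    unclass(generate_cohort(plan, hypnogram_params(), shifted_physio_params(),
                            transform = function(rec) {
                              rec$resp <- extract_resp(rec$accel)
                              resample_to_model_grid(rec, grid)
                            }))
  })
}

pooled_kappa <- function(model, inputs, modalities = c("ecg", "resp")) {
  pr <- do.call(rbind, lapply(inputs, function(inp) {
    post <- predict_stages(model, inp, modalities)
    k <- which(inp$loss_mask)
    data.frame(t = as.character(inp$labels)[k],
               p = as.character(post$stages)[k])
  }))
  cohens_kappa(confusion(hypnogram(pr$t), hypnogram(pr$p)))
}

# The scratch-trained reduced model on the learnability cohort: trained
# once, reused by the learnability and transfer checks.
scratch_fit <- function() {
  fixture("scratch_fit", function() {
    inputs <- learnability_inputs()
    pids <- vapply(inputs, function(x) x$participant_id, character(1))
    tr <- inputs[pids %in% sprintf("P%02d", 1:10)]
    va <- inputs[pids == "P11"]
    te <- inputs[pids == "P12"]
    cfg <- reduced_model_config()
    model <- build_model(cfg, seed = 7)
    tc <- train_config(learning_rate = 1e-3, batch_size = 8, patience = 5,
                       max_epochs = 15, seed = 7)
    ft <- fit_model(model, tr, va, tc)
    list(fit = ft, train = tr, val = va, test = te)
  })
}
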