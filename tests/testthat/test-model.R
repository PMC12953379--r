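# Architecture contracts, locality, attention reach, gradients.

test_that("configuration invariants tie encoder depth to input length", {
  cfg <- model_config()
  expect_equal(2^8 * 4800, 1228800)
  expect_equal(cfg$ecg_len, 1228800)
  expect_equal(cfg$resp_len, 307200)
  expect_equal(cfg$fused_dim, 1024)
  expect_equal(cfg$encoder_out_channels, 256)
  # mismatched encoder tails are rejected
  expect_error(model_config(resp_encoder_features = c(16, 32, 64, 64, 128, 64)))
})

test_that("encoder, fusion and heads produce the documented shapes (reduced)", {
  cfg <- reduced_model_config()
  m <- build_model(cfg, seed = 1)
  set.seed(1)
  en <- encode_signal(stats::rnorm(cfg$ecg_len), "ecg", m)
  expect_equal(dim(en$y), c(cfg$n_epochs * 4, cfg$encoder_out_channels))
  er <- encode_signal(stats::rnorm(cfg$resp_len), "resp", m)
  expect_equal(dim(er$y), dim(en$y))
  fu <- fuse_per_epoch(en$y, "ecg", m)
  expect_equal(dim(fu$y), c(cfg$n_epochs, cfg$epoch_feature_dim))

  expect_error(encode_signal(stats::rnorm(10), "ecg", m), "expected 61440")
})

test_that("time-distributed fusion is epoch-local", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 3)
  set.seed(3)
  feat <- matrix(stats::rnorm(cfg$n_epochs * cfg$frames_per_epoch *
                                cfg$encoder_out_channels),
                 cfg$n_epochs * cfg$frames_per_epoch, cfg$encoder_out_channels)
  y1 <- fuse_per_epoch(feat, "ecg", m)$y
  # swap the frames of epochs 1 and 3
  f <- cfg$frames_per_epoch
  idx <- seq_len(nrow(feat))
  e1 <- 1:f
  e3 <- (2 * f + 1):(3 * f)
  idx[c(e1, e3)] <- idx[c(e3, e1)]
  y2 <- fuse_per_epoch(feat[idx, ], "ecg", m)$y
  expect_equal(y2[c(1, 3), ], y1[c(3, 1), ])
  expect_equal(y2[c(2, 4), ], y1[c(2, 4), ])

  # shared weights: constant input rows give identical output rows
  yc <- fuse_per_epoch(matrix(1, nrow(feat), ncol(feat)), "ecg", m)$y
  expect_equal(max(abs(sweep(yc, 2, yc[1, ]))), 0)
})

test_that("epoch mixer accepts one or two modalities and is deterministic in eval", {
  cfg <- reduced_model_config()
  m <- build_model(cfg, seed = 2)
  set.seed(2)
  map_e <- matrix(stats::rnorm(cfg$n_epochs * cfg$epoch_feature_dim),
                  cfg$n_epochs, cfg$epoch_feature_dim)
  map_r <- matrix(stats::rnorm(cfg$n_epochs * cfg$epoch_feature_dim),
                  cfg$n_epochs, cfg$epoch_feature_dim)
  y_both <- epoch_mixer(list(ecg = map_e, resp = map_r), m)$y
  y_ecg <- epoch_mixer(list(ecg = map_e), m)$y
  expect_equal(dim(y_both), dim(map_e))
  expect_equal(dim(y_ecg), dim(map_e))
  expect_false(isTRUE(all.equal(y_both, y_ecg)))
  expect_identical(epoch_mixer(list(ecg = map_e), m)$y, y_ecg)
  expect_error(epoch_mixer(list(), m), "at least one")
})

test_that("attention gives the first epoch reach to the last", {
  cfg <- reduced_model_config()
  m <- build_model(cfg, seed = 4)
  set.seed(4)
  map <- matrix(stats::rnorm(cfg$n_epochs * cfg$epoch_feature_dim),
                cfg$n_epochs, cfg$epoch_feature_dim)
  y0 <- epoch_mixer(list(ecg = map), m)$y
  map2 <- map
  map2[1, ] <- map2[1, ] + 1
  y1 <- epoch_mixer(list(ecg = map2), m)$y
  expect_gt(max(abs(y1[cfg$n_epochs, ] - y0[cfg$n_epochs, ])), 1e-8)
})

test_that("dilated stack's receptive field matches the dilation schedule", {
  cfg <- model_config()
  # analytic receptive field: 1 + (kernel-1) * sum(dilations)
  rf_expected <- 1 + (cfg$seq_kernel - 1) * sum(cfg$seq_dilations)
  expect_equal(rf_expected, 757)

  # impulse oracle through the configured convolution stack
  m <- build_model(reduced_model_config(n_epochs = 1200), seed = 5)
  x0 <- matrix(0, 1200, m$cfg$seq_features)
  x1 <- x0
  x1[600, ] <- 1
  h0 <- x0
  h1 <- x1
  for (i in seq_along(m$cfg$seq_dilations)) {
    h0 <- conv1d_fwd(h0, m$params$seq[[i]]$conv, m$cfg$seq_dilations[i])$y
    h1 <- conv1d_fwd(h1, m$params$seq[[i]]$conv, m$cfg$seq_dilations[i])$y
  }
  affected <- which(rowSums(abs(h1 - h0)) > 1e-12)
  expect_equal(length(affected), 757)
  expect_equal(range(affected), c(600 - 378, 600 + 378))
})

test_that("forward pass: posterior rows normalize; zero input stays finite", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, seed = 6)
  inp <- random_model_input(cfg, seed = 6)
  post <- predict_stages(m, inp)
  expect_equal(dim(post$logits), c(cfg$n_epochs, 4))
  expect_true(all(abs(rowSums(post$probabilities) - 1) < 1e-6))
  expect_true(all(as.character(post$stages) %in% SLEEP_STAGES))

  z <- list(ecg = numeric(cfg$ecg_len), resp = numeric(cfg$resp_len),
            labels = inp$labels, loss_mask = inp$loss_mask)
  expect_true(all(is.finite(model_forward(m, z)$logits)))

  # ECG-only and ECG+RESP pathways both produce full posteriors
  p_ecg <- predict_stages(m, inp, "ecg")
  expect_equal(dim(p_ecg$logits), dim(post$logits))
})

test_that("two builds with the same seed are identical; parameter count stable", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  expect_equal(count_parameters(m1), count_parameters(m2))
  m3 <- build_model(cfg, seed = 12)
  expect_false(identical(m1$params, m3$params))
})

test_that("analytic gradients match finite differences through the whole model", {
  cfg <- tiny_model_config(mixer_dropout = 0)
  m <- build_model(cfg, seed = 2)
  inp <- random_model_input(cfg, seed = 9)
  lab <- stage_index(inp$labels)
  loss_at <- function(model) {
    fw <- model_forward(model, inp, train = FALSE, keep_cache = TRUE)
    masked_ce_loss(fw$logits, lab, inp$loss_mask)
  }
  r <- loss_at(m)
  fw <- model_forward(m, inp, train = FALSE, keep_cache = TRUE)
  grads <- model_backward(m, fw$cache, r$dlogits)
  gv <- tree_flatten(grads)
  pv <- tree_flatten(m$params)
  set.seed(13)
  idx <- sort(sample(length(pv), 60))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    up <- pv; up[i] <- up[i] + eps
    dn <- pv; dn[i] <- dn[i] - eps
    mu <- m; mu$params <- tree_unflatten(m$params, up)
    md <- m; md$params <- tree_unflatten(m$params, dn)
    (loss_at(mu)$loss - loss_at(md)$loss) / (2 * eps)
  }, numeric(1))
  relerr <- abs(num - gv[idx]) / pmax(1e-6, abs(num) + abs(gv[idx]))
  expect_lt(max(relerr), 1e-3)
})

test_that("masked epochs contribute exactly zero gradient", {
  cfg <- tiny_model_config(mixer_dropout = 0)
  m <- build_model(cfg, seed = 3)
  stages <- c("WAKE", "ARTIFACT", "N3", "PAD")
  inp <- random_model_input(cfg, seed = 10, stages = stages)
  fw <- model_forward(m, inp, keep_cache = TRUE)
  ls <- masked_ce_loss(fw$logits, stage_index(inp$labels), inp$loss_mask)
  expect_true(all(ls$dlogits[c(2, 4), ] == 0))
  # changing a masked epoch's (absent) label cannot change the loss
  lab2 <- stage_index(inp$labels)
  lab2[2] <- 4L
  expect_equal(masked_ce_loss(fw$logits, lab2, inp$loss_mask)$loss, ls$loss)
})
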