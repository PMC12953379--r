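# Whole-night cardiorespiratory staging model: per-modality residual
# convolutional encoders -> per-epoch fusion -> transformer epoch mixer
# -> dilated-convolution sequence mixer -> per-epoch 4-class head.

#' Staging-model configuration
#'
#' All architecture constants in one place. The defaults reproduce the
#' published whole-night configuration: a 10-h window of 1,200 epochs;
#' an ECG encoder of eight residual blocks (features 16,16,32,32,64,64,
#' 128,128; three kernel-3 convolutions per block, each block followed by
#' factor-2 max pooling) consuming 1,228,800 samples; a respiratory
#' encoder of six blocks (16,32,64,64,128,128) consuming 307,200
#' samples; both encoders emit 4,800 x 256 feature maps (a final
#' kernel-1 channel-doubling convolution maps the last block's 128
#' features to the 256-channel output width). Features are regrouped
#' per epoch (4 frames x 256 channels = 1,024), reduced to 128 per epoch
#' by a time-distributed dense layer, fused across modalities by
#' summation (with a learned null vector standing in for an absent
#' modality), passed through two transformer encoder blocks (8 heads,
#' feed-forward width 512, dropout 0.1, sinusoidal positional encoding)
#' attending over all 1,200 epochs, then through twelve dilated
#' convolution layers (kernel 7, 128 features, dilations 1,2,4,8,16,32
#' repeated twice, residual connections) and a dense 128 -> 4 head.
#'
#' @param n_epochs Epochs per model window.
#' @param ecg_encoder_features Integer vector: channels per ECG residual
#'   block (one pooling per block).
#' @param resp_encoder_features Channels per respiratory residual block.
#' @param frames_per_epoch Encoder output frames grouped per epoch.
#' @param conv_kernel Encoder convolution kernel size.
#' @param convs_per_block Convolutions per residual block.
#' @param pool_factor Pooling factor per block.
#' @param encoder_out_multiple Channel multiple of the final kernel-1
#'   encoder convolution relative to the last block.
#' @param epoch_feature_dim Per-epoch feature width after fusion.
#' @param mixer_blocks,mixer_heads,mixer_ff_dim,mixer_dropout Transformer
#'   epoch-mixer hyper-parameters.
#' @param seq_dilations Dilation schedule of the sequence mixer.
#' @param seq_kernel,seq_features Sequence-mixer kernel size and width.
#' @param n_classes Output classes (4: WAKE/N1N2/N3/REM).
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_epochs = 1200,
                         ecg_encoder_features = c(16, 16, 32, 32, 64, 64, 128, 128),
                         resp_encoder_features = c(16, 32, 64, 64, 128, 128),
                         frames_per_epoch = 4,
                         conv_kernel = 3,
                         convs_per_block = 3,
                         pool_factor = 2,
                         encoder_out_multiple = 2,
                         epoch_feature_dim = 128,
                         mixer_blocks = 2,
                         mixer_heads = 8,
                         mixer_ff_dim = 512,
                         mixer_dropout = 0.1,
                         seq_dilations = rep(c(1, 2, 4, 8, 16, 32), 2),
                         seq_kernel = 7,
                         seq_features = 128,
                         n_classes = 4) {
  cfg <- list(n_epochs = n_epochs,
              ecg_encoder_features = ecg_encoder_features,
              resp_encoder_features = resp_encoder_features,
              frames_per_epoch = frames_per_epoch,
              conv_kernel = conv_kernel,
              convs_per_block = convs_per_block,
              pool_factor = pool_factor,
              encoder_out_multiple = encoder_out_multiple,
              epoch_feature_dim = epoch_feature_dim,
              mixer_blocks = mixer_blocks, mixer_heads = mixer_heads,
              mixer_ff_dim = mixer_ff_dim, mixer_dropout = mixer_dropout,
              seq_dilations = seq_dilations, seq_kernel = seq_kernel,
              seq_features = seq_features, n_classes = n_classes)
  cfg$ecg_len <- n_epochs * frames_per_epoch *
    pool_factor^length(ecg_encoder_features)
  cfg$resp_len <- n_epochs * frames_per_epoch *
    pool_factor^length(resp_encoder_features)
  cfg$encoder_out_channels <- encoder_out_multiple *
    utils::tail(ecg_encoder_features, 1)
  stopifnot(cfg$encoder_out_channels ==
              encoder_out_multiple * utils::tail(resp_encoder_features, 1),
            epoch_feature_dim %% mixer_heads == 0,
            seq_features == epoch_feature_dim)
  cfg$fused_dim <- frames_per_epoch * cfg$encoder_out_channels
  structure(cfg, class = "model_config")
}

#' Width-reduced configuration for desk-scale training
#'
#' Same architecture shape (residual encoder ladders, channel-doubling
#' head, two transformer blocks, twelve dilated layers) at reduced
#' width and window length, for CPU-scale experiments on synthetic
#' cohorts: 2-h windows (240 epochs), ECG at 256 samples/epoch
#' (8.53 Hz, six blocks), respiration at 64 samples/epoch (2.13 Hz,
#' four blocks), 32 features per epoch.
#'
#' @param n_epochs Epochs per window (default 240 = 2 h).
#' @param ... Overrides passed to [model_config()].
#' @return `model_config`.
#' @export
reduced_model_config <- function(n_epochs = 240, ...) {
  model_config(n_epochs = n_epochs,
               ecg_encoder_features = c(4, 4, 8, 8, 16, 16),
               resp_encoder_features = c(4, 8, 16, 16),
               epoch_feature_dim = 32,
               mixer_heads = 4, mixer_ff_dim = 128,
               seq_features = 32, ...)
}

#' Model grid matching a model configuration
#' @param cfg [model_config].
#' @return [model_grid] with the configuration's input lengths.
#' @export
grid_for_config <- function(cfg) {
  model_grid(n_epochs = cfg$n_epochs,
             ecg_samples_per_epoch = cfg$ecg_len / cfg$n_epochs,
             resp_samples_per_epoch = cfg$resp_len / cfg$n_epochs)
}

## ---- construction --------------------------------------------------------

init_block <- function(k, cin, cout) {
  b <- list(c1 = init_conv(k, cin, cout), n1 = init_norm(cout),
            c2 = init_conv(k, cout, cout), n2 = init_norm(cout),
            c3 = init_conv(k, cout, cout), n3 = init_norm(cout))
  if (cin != cout) b$proj <- init_conv(1, cin, cout)
  b
}

init_encoder <- function(features, cfg) {
  cin <- 1
  blocks <- vector("list", length(features))
  for (i in seq_along(features)) {
    blocks[[i]] <- init_block(cfg$conv_kernel, cin, features[i])
    cin <- features[i]
  }
  list(blocks = blocks,
       head = list(conv = init_conv(1, cin, cfg$encoder_out_channels),
                   norm = init_norm(cfg$encoder_out_channels)))
}

init_mixer_block <- function(d, ff) {
  list(attn = init_attention(d),
       ln1 = init_norm(d),
       ff1 = init_dense(d, ff),
       ff2 = init_dense(ff, d),
       ln2 = init_norm(d))
}

#' Build a staging model
#'
#' Initializes all weights (He fan-in for convolutions and dense layers)
#' under `seed`, so two builds with the same configuration and seed are
#' identical.
#'
#' @param cfg [model_config].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `sleep_model`: list with `cfg` and `params`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, {
    params <- list(
      enc_ecg = init_encoder(cfg$ecg_encoder_features, cfg),
      enc_resp = init_encoder(cfg$resp_encoder_features, cfg),
      fuse_ecg = init_dense(cfg$fused_dim, cfg$epoch_feature_dim),
      fuse_resp = init_dense(cfg$fused_dim, cfg$epoch_feature_dim),
      null_ecg = numeric(cfg$epoch_feature_dim),
      null_resp = numeric(cfg$epoch_feature_dim),
      mixer = lapply(seq_len(cfg$mixer_blocks), function(i)
        init_mixer_block(cfg$epoch_feature_dim, cfg$mixer_ff_dim)),
      seq = lapply(seq_along(cfg$seq_dilations), function(i)
        list(conv = init_conv(cfg$seq_kernel, cfg$seq_features, cfg$seq_features),
             norm = init_norm(cfg$seq_features))),
      out = init_dense(cfg$seq_features, cfg$n_classes))
    structure(list(cfg = cfg, params = params,
                   posenc = positional_encoding(cfg$n_epochs, cfg$epoch_feature_dim)),
              class = "sleep_model")
  })
}

#' Number of trainable parameters
#' @param model [build_model()] result.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  tree_reduce_sum(length, model$params)
}

#' @export
print.sleep_model <- function(x, ...) {
  cat(sprintf("<sleep_model> %d epochs/window, %d features/epoch, %s parameters\n",
              x$cfg$n_epochs, x$cfg$epoch_feature_dim,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

## ---- encoder forward/backward -------------------------------------------

block_fwd <- function(x, p) {
  a1 <- conv1d_fwd(x, p$c1)
  n1 <- norm_time_fwd(a1$y, p$n1)
  r1 <- relu_fwd(n1$y)
  a2 <- conv1d_fwd(r1$y, p$c2)
  n2 <- norm_time_fwd(a2$y, p$n2)
  r2 <- relu_fwd(n2$y)
  a3 <- conv1d_fwd(r2$y, p$c3)
  n3 <- norm_time_fwd(a3$y, p$n3)
  skip <- if (is.null(p$proj)) list(y = x) else conv1d_fwd(x, p$proj)
  r3 <- relu_fwd(n3$y + skip$y)
  pl <- maxpool2_fwd(r3$y)
  list(y = pl$y, cache = list(a1 = a1, n1 = n1, r1 = r1, a2 = a2, n2 = n2,
                              r2 = r2, a3 = a3, n3 = n3, skip = skip,
                              r3 = r3, pl = pl))
}

block_bwd <- function(dy, cache, p) {
  d <- maxpool2_bwd(dy, cache$pl)
  d <- relu_bwd(d, cache$r3)
  g <- list()
  if (is.null(p$proj)) {
    dskip <- d
  } else {
    bs <- conv1d_bwd(d, cache$skip, p$proj)
    dskip <- bs$dx
    g$proj <- bs$grads
  }
  b3 <- norm_time_bwd(d, cache$n3, p$n3)
  g$n3 <- b3$grads
  c3 <- conv1d_bwd(b3$dx, cache$a3, p$c3)
  g$c3 <- c3$grads
  d2 <- relu_bwd(c3$dx, cache$r2)
  b2 <- norm_time_bwd(d2, cache$n2, p$n2)
  g$n2 <- b2$grads
  c2 <- conv1d_bwd(b2$dx, cache$a2, p$c2)
  g$c2 <- c2$grads
  d1 <- relu_bwd(c2$dx, cache$r1)
  b1 <- norm_time_bwd(d1, cache$n1, p$n1)
  g$n1 <- b1$grads
  c1 <- conv1d_bwd(b1$dx, cache$a1, p$c1)
  g$c1 <- c1$grads
  list(dx = c1$dx + dskip, grads = g[c("c1", "n1", "c2", "n2", "c3", "n3",
                                       if (!is.null(p$proj)) "proj")])
}

#' Encode a raw modality waveform into per-frame features
#'
#' Applies the modality's residual-block ladder. Input length must equal
#' the configuration's expected length for the modality; output is
#' `n_epochs * frames_per_epoch` rows by `encoder_out_channels` columns.
#'
#' @param x Numeric waveform vector.
#' @param modality `"ecg"` or `"resp"`.
#' @param model [build_model()] result.
#' @param keep_cache Keep per-layer caches for backprop?
#' @return List with `y` (feature matrix) and `cache`.
#' @export
encode_signal <- function(x, modality = c("ecg", "resp"), model,
                          keep_cache = FALSE) {
  modality <- match.arg(modality)
  cfg <- model$cfg
  expected <- if (modality == "ecg") cfg$ecg_len else cfg$resp_len
  if (length(x) != expected) {
    stop(sprintf("%s input has %d samples; expected %d",
                 toupper(modality), length(x), expected))
  }
  enc <- model$params[[paste0("enc_", modality)]]
  h <- matrix(x, ncol = 1)
  caches <- vector("list", length(enc$blocks))
  for (i in seq_along(enc$blocks)) {
    st <- block_fwd(h, enc$blocks[[i]])
    h <- st$y
    caches[[i]] <- if (keep_cache) st$cache else NULL
  }
  hc <- conv1d_fwd(h, enc$head$conv)
  hn <- norm_time_fwd(hc$y, enc$head$norm)
  hr <- relu_fwd(hn$y)
  list(y = hr$y,
       cache = if (keep_cache) list(blocks = caches, hc = hc, hn = hn, hr = hr)
               else NULL)
}

encoder_bwd <- function(dy, cache, enc) {
  hr <- relu_bwd(dy, cache$hr)
  hn <- norm_time_bwd(hr, cache$hn, enc$head$norm)
  hc <- conv1d_bwd(hn$dx, cache$hc, enc$head$conv)
  g <- list(blocks = vector("list", length(enc$blocks)),
            head = list(conv = hc$grads, norm = hn$grads))
  d <- hc$dx
  for (i in rev(seq_along(enc$blocks))) {
    bb <- block_bwd(d, cache$blocks[[i]], enc$blocks[[i]])
    d <- bb$dx
    g$blocks[[i]] <- bb$grads
  }
  g
}

## ---- per-epoch regrouping + fusion dense --------------------------------

#' Regroup encoder frames per epoch and reduce to epoch features
#'
#' Reshapes the `(n_epochs * frames)` x `channels` feature map to
#' `n_epochs` x `(frames * channels)` (epoch-local frames concatenated)
#' and applies a shared time-distributed dense map to
#' `epoch_feature_dim` features per epoch.
#'
#' @param feat Encoder output matrix.
#' @param modality `"ecg"` or `"resp"`.
#' @param model [build_model()] result.
#' @param keep_cache Keep caches for backprop?
#' @return List with `y` (`n_epochs` x `epoch_feature_dim`) and `cache`.
#' @export
fuse_per_epoch <- function(feat, modality = c("ecg", "resp"), model,
                           keep_cache = FALSE) {
  modality <- match.arg(modality)
  cfg <- model$cfg
  f <- cfg$frames_per_epoch
  if (nrow(feat) %% f != 0 || nrow(feat) / f != cfg$n_epochs) {
    stop(sprintf("feature map has %d rows; expected %d epochs x %d frames",
                 nrow(feat), cfg$n_epochs, f))
  }
  ch <- ncol(feat)
  # Row e of Z concatenates the f frames of epoch e.
  Z <- matrix(0, cfg$n_epochs, f * ch)
  for (j in seq_len(f)) {
    Z[, ((j - 1) * ch + 1):(j * ch)] <- feat[seq(j, nrow(feat), by = f), ]
  }
  dn <- dense_fwd(Z, model$params[[paste0("fuse_", modality)]])
  list(y = dn$y, cache = if (keep_cache) list(dn = dn, f = f, ch = ch) else NULL)
}

fuse_bwd <- function(dy, cache, p) {
  dd <- dense_bwd(dy, cache$dn, p)
  f <- cache$f
  ch <- cache$ch
  dfeat <- matrix(0, nrow(dy) * f, ch)
  for (j in seq_len(f)) {
    dfeat[seq(j, nrow(dfeat), by = f), ] <- dd$dx[, ((j - 1) * ch + 1):(j * ch)]
  }
  list(dfeat = dfeat, grads = dd$grads)
}

## ---- epoch mixer ---------------------------------------------------------

mixer_block_fwd <- function(x, p, cfg, train) {
  at <- attention_fwd(x, p$attn, cfg$mixer_heads)
  do1 <- dropout_fwd(at$y, cfg$mixer_dropout, train)
  l1 <- layernorm_fwd(x + do1$y, p$ln1)
  f1 <- dense_fwd(l1$y, p$ff1)
  r1 <- relu_fwd(f1$y)
  f2 <- dense_fwd(r1$y, p$ff2)
  do2 <- dropout_fwd(f2$y, cfg$mixer_dropout, train)
  l2 <- layernorm_fwd(l1$y + do2$y, p$ln2)
  list(y = l2$y, cache = list(at = at, do1 = do1, l1 = l1, f1 = f1,
                              r1 = r1, f2 = f2, do2 = do2, l2 = l2))
}

mixer_block_bwd <- function(dy, cache, p) {
  b2 <- layernorm_bwd(dy, cache$l2, p$ln2)
  g <- list()
  g$ln2 <- b2$grads
  dff <- dropout_bwd(b2$dx, cache$do2)
  bf2 <- dense_bwd(dff, cache$f2, p$ff2)
  g$ff2 <- bf2$grads
  dr <- relu_bwd(bf2$dx, cache$r1)
  bf1 <- dense_bwd(dr, cache$f1, p$ff1)
  g$ff1 <- bf1$grads
  dl1 <- b2$dx + bf1$dx
  b1 <- layernorm_bwd(dl1, cache$l1, p$ln1)
  g$ln1 <- b1$grads
  datt <- dropout_bwd(b1$dx, cache$do1)
  ba <- attention_bwd(datt, cache$at, p$attn)
  g$attn <- ba$grads
  list(dx = b1$dx + ba$dx, grads = g[c("attn", "ln1", "ff1", "ff2", "ln2")])
}

#' Fuse modality maps and mix epochs with transformer blocks
#'
#' Sums the per-modality epoch feature maps (a learned null vector
#' stands in for each absent modality), adds sinusoidal positional
#' encoding, and applies the configured number of transformer encoder
#' blocks attending over the whole window.
#'
#' @param maps Named list of `n_epochs` x `epoch_feature_dim` matrices
#'   (names among `"ecg"`, `"resp"`); at least one required.
#' @param model [build_model()] result.
#' @param train Training mode (enables dropout)?
#' @param keep_cache Keep caches for backprop?
#' @return List with `y` and `cache`.
#' @export
epoch_mixer <- function(maps, model, train = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  if (length(maps) == 0) stop("epoch_mixer needs at least one modality map")
  x <- model$posenc
  for (m in c("ecg", "resp")) {
    x <- x + if (!is.null(maps[[m]])) maps[[m]]
         else matrix(model$params[[paste0("null_", m)]],
                     cfg$n_epochs, cfg$epoch_feature_dim, byrow = TRUE)
  }
  caches <- vector("list", cfg$mixer_blocks)
  for (i in seq_len(cfg$mixer_blocks)) {
    st <- mixer_block_fwd(x, model$params$mixer[[i]], cfg, train)
    x <- st$y
    caches[[i]] <- if (keep_cache) st$cache else NULL
  }
  list(y = x, cache = if (keep_cache) caches else NULL)
}

## ---- sequence mixer ------------------------------------------------------

#' Sequence mixer: dilated residual convolutions + per-epoch class head
#'
#' Twelve dilated convolution layers (kernel `seq_kernel`, residual
#' connections, normalization + ReLU) over the epoch axis, followed by a
#' shared dense map to class logits.
#'
#' @param z `n_epochs` x `epoch_feature_dim` matrix.
#' @param model [build_model()] result.
#' @param keep_cache Keep caches for backprop?
#' @return List with `logits` and `cache`.
#' @export
sequence_mixer <- function(z, model, keep_cache = FALSE) {
  cfg <- model$cfg
  if (ncol(z) != cfg$seq_features || nrow(z) != cfg$n_epochs) {
    stop(sprintf("sequence mixer expects %d x %d input",
                 cfg$n_epochs, cfg$seq_features))
  }
  caches <- vector("list", length(cfg$seq_dilations))
  x <- z
  for (i in seq_along(cfg$seq_dilations)) {
    p <- model$params$seq[[i]]
    cv <- conv1d_fwd(x, p$conv, dilation = cfg$seq_dilations[i])
    nm <- norm_time_fwd(cv$y, p$norm)
    rl <- relu_fwd(nm$y)
    caches[[i]] <- if (keep_cache) list(cv = cv, nm = nm, rl = rl) else NULL
    x <- x + rl$y
  }
  out <- dense_fwd(x, model$params$out)
  list(logits = out$y,
       cache = if (keep_cache) list(layers = caches, out = out) else NULL)
}

sequence_mixer_bwd <- function(dlogits, cache, model) {
  cfg <- model$cfg
  bo <- dense_bwd(dlogits, cache$out, model$params$out)
  g <- list(seq = vector("list", length(cfg$seq_dilations)), out = bo$grads)
  d <- bo$dx
  for (i in rev(seq_along(cfg$seq_dilations))) {
    p <- model$params$seq[[i]]
    cc <- cache$layers[[i]]
    dr <- relu_bwd(d, cc$rl)
    bn <- norm_time_bwd(dr, cc$nm, p$norm)
    bc <- conv1d_bwd(bn$dx, cc$cv, p$conv, dilation = cfg$seq_dilations[i])
    g$seq[[i]] <- list(conv = bc$grads, norm = bn$grads)
    d <- d + bc$dx          # residual path
  }
  list(dz = d, grads = g)
}

## ---- full model ----------------------------------------------------------

#' Forward pass over one night
#'
#' @param model [build_model()] result.
#' @param input [resample_to_model_grid()] result (`model_input`), or a
#'   list with `ecg` and optionally `resp` vectors of the configured
#'   lengths.
#' @param modalities Character subset of `c("ecg", "resp")`.
#' @param train Training mode (dropout active)?
#' @param keep_cache Keep caches for backprop?
#' @return List with `logits` (`n_epochs` x `n_classes`) and `cache`.
#' @export
model_forward <- function(model, input, modalities = c("ecg", "resp"),
                          train = FALSE, keep_cache = FALSE) {
  stopifnot(inherits(model, "sleep_model"))
  modalities <- intersect(modalities, c("ecg", "resp"))
  if (is.null(input$resp)) modalities <- setdiff(modalities, "resp")
  if (length(modalities) == 0) stop("no modalities available for forward pass")
  maps <- list()
  caches <- list()
  for (m in modalities) {
    en <- encode_signal(input[[m]], m, model, keep_cache = keep_cache)
    fu <- fuse_per_epoch(en$y, m, model, keep_cache = keep_cache)
    maps[[m]] <- fu$y
    caches[[m]] <- list(enc = en$cache, fuse = fu$cache)
  }
  mx <- epoch_mixer(maps, model, train = train, keep_cache = keep_cache)
  sq <- sequence_mixer(mx$y, model, keep_cache = keep_cache)
  list(logits = sq$logits,
       cache = if (keep_cache) list(modalities = modalities, enc = caches,
                                    mixer = mx$cache, seqm = sq$cache)
               else NULL)
}

model_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  grads <- zeros_like(model$params)
  sb <- sequence_mixer_bwd(dlogits, cache$seqm, model)
  grads$seq <- sb$grads$seq
  grads$out <- sb$grads$out
  d <- sb$dz
  for (i in rev(seq_len(cfg$mixer_blocks))) {
    mb <- mixer_block_bwd(d, cache$mixer[[i]], model$params$mixer[[i]])
    grads$mixer[[i]] <- mb$grads
    d <- mb$dx
  }
  for (m in c("ecg", "resp")) {
    if (m %in% cache$modalities) {
      fb <- fuse_bwd(d, cache$enc[[m]]$fuse, model$params[[paste0("fuse_", m)]])
      grads[[paste0("fuse_", m)]] <- fb$grads
      grads[[paste0("enc_", m)]] <-
        encoder_bwd(fb$dfeat, cache$enc[[m]]$enc,
                    model$params[[paste0("enc_", m)]])
    } else {
      grads[[paste0("null_", m)]] <- colSums(d)
    }
  }
  grads
}

#' Masked cross-entropy loss and its logit gradient
#'
#' Mean negative log-likelihood over epochs whose mask is `TRUE`
#' (ARTIFACT and PAD epochs contribute exactly zero gradient).
#'
#' @param logits `n_epochs` x `n_classes` matrix.
#' @param label_idx Integer class indices (NA where unscored).
#' @param mask Logical vector of scoreable epochs.
#' @return List with `loss` and `dlogits`.
#' @export
masked_ce_loss <- function(logits, label_idx, mask) {
  n <- nrow(logits)
  m <- which(mask & !is.na(label_idx))
  if (length(m) == 0) return(list(loss = NA_real_, dlogits = logits * 0))
  lg <- logits - apply(logits, 1, max)
  el <- exp(lg)
  p <- el / rowSums(el)
  ll <- lg[cbind(m, label_idx[m])] - log(rowSums(el))[m]
  dlogits <- matrix(0, n, ncol(logits))
  dlogits[m, ] <- p[m, , drop = FALSE] / length(m)
  dlogits[cbind(m, label_idx[m])] <- dlogits[cbind(m, label_idx[m])] -
    1 / length(m)
  list(loss = -mean(ll), dlogits = dlogits)
}

#' Per-epoch stage posterior for one night
#'
#' @param model [build_model()] result.
#' @param input `model_input`.
#' @param modalities Modalities to use.
#' @return Object of class `stage_posterior`: list with `logits`,
#'   `probabilities` (rows sum to 1) and `stages` ([hypnogram] of argmax
#'   labels).
#' @export
predict_stages <- function(model, input, modalities = c("ecg", "resp")) {
  fw <- model_forward(model, input, modalities, train = FALSE)
  lg <- fw$logits - apply(fw$logits, 1, max)
  el <- exp(lg)
  probs <- el / rowSums(el)
  colnames(probs) <- SLEEP_STAGES
  structure(list(logits = fw$logits, probabilities = probs,
                 stages = hypnogram(SLEEP_STAGES[max.col(probs, ties.method = "first")])),
            class = "stage_posterior")
}
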