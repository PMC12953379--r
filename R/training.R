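# Training harness: AdamW, early stopping with best-weight reversion,
# leave-one-subject-out cross-validation, transfer learning.

#' Training configuration
#'
#' Whole nights are the batch unit: gradients are averaged over
#' `batch_size` nights per optimizer step (gradient accumulation, since
#' the model consumes one full window at a time). Early stopping halts
#' training when the validation loss has not improved on its running
#' minimum for `patience` consecutive validation evaluations (one per
#' training epoch), after which the weights revert to the
#' minimum-validation-loss state.
#'
#' @param learning_rate Fixed learning rate (1e-5 for transfer
#'   fine-tuning; ~1e-3 for training from scratch).
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Nights per optimizer step.
#' @param patience Validation evaluations without improvement before
#'   stopping.
#' @param max_epochs Hard cap on training epochs.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param modalities Modalities used for training and prediction.
#' @param seed RNG seed (shuffling, dropout).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, weight_decay = 0.01,
                         batch_size = 16, patience = 5, max_epochs = 100,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         modalities = c("ecg", "resp"), seed = 1L) {
  stopifnot(patience >= 1, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = batch_size, patience = patience,
                 max_epochs = max_epochs, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, modalities = modalities,
                 seed = as.integer(seed)),
            class = "train_config")
}

# One AdamW update; params/grads/state are parallel trees.
adamw_step <- function(params, grads, state, cfg, step) {
  state$m <- tree_map(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - cfg$beta1^step
  bc2 <- 1 - cfg$beta2^step
  params <- tree_map(function(p, m, v) {
    p - cfg$learning_rate *
      ((m / bc1) / (sqrt(v / bc2) + cfg$adam_eps) + cfg$weight_decay * p)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

#' Early-stopping decision on a validation-loss sequence
#'
#' Implements the patience rule used by [fit_model()]: the best epoch is
#' the first minimum of the sequence; training stops after the epoch at
#' which `patience` consecutive evaluations have failed to improve
#' strictly on the running minimum.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving evaluations tolerated.
#' @return List with `stop_epoch` (last epoch run, `NA` if the sequence
#'   never triggers stopping) and `best_epoch` (whose weights are kept).
#' @export
early_stopping_plan <- function(val_losses, patience) {
  best <- Inf
  best_epoch <- NA_integer_
  bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = NA_integer_, best_epoch = best_epoch)
}

night_loss <- function(model, inp, modalities) {
  fw <- model_forward(model, inp, modalities, train = FALSE)
  masked_ce_loss(fw$logits, stage_index(inp$labels), inp$loss_mask)$loss
}

#' Fit a staging model
#'
#' Minimizes masked cross-entropy with AdamW over whole-night batches.
#' After each pass over the training set the validation loss is
#' evaluated; on stopping, weights revert to the minimum-validation-loss
#' state. Nights whose loss mask is empty are skipped with a warning.
#'
#' @param model [build_model()] result (starting point: fresh weights
#'   for scratch training, a pretrained checkpoint for transfer).
#' @param train_inputs,val_inputs Lists of `model_input`.
#' @param cfg [train_config()].
#' @param quiet Suppress per-epoch progress?
#' @return List with `model` (best weights), `history` (data.frame of
#'   per-epoch train/val losses) and `best_epoch`.
#' @export
fit_model <- function(model, train_inputs, val_inputs, cfg = train_config(),
                      quiet = TRUE) {
  stopifnot(length(train_inputs) > 0, length(val_inputs) > 0)
  with_seed(cfg$seed, {
    state <- list(m = zeros_like(model$params), v = zeros_like(model$params))
    step <- 0L
    val_hist <- numeric(0)
    train_hist <- numeric(0)
    best_params <- model$params
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(train_inputs))
      ep_losses <- numeric(0)
      acc_grads <- NULL
      n_acc <- 0L
      flush <- function() {
        if (n_acc == 0L) return()
        g <- tree_map(function(a) a / n_acc, acc_grads)
        step <<- step + 1L
        upd <- adamw_step(model$params, g, state, cfg, step)
        model$params <<- upd$params
        state <<- upd$state
        acc_grads <<- NULL
        n_acc <<- 0L
      }
      for (i in ord) {
        inp <- train_inputs[[i]]
        if (!any(inp$loss_mask)) {
          warning(sprintf("night %s/%s has an empty loss mask; skipped",
                          inp$participant_id, inp$night_label))
          next
        }
        fw <- model_forward(model, inp, cfg$modalities,
                            train = TRUE, keep_cache = TRUE)
        ls <- masked_ce_loss(fw$logits, stage_index(inp$labels), inp$loss_mask)
        ep_losses <- c(ep_losses, ls$loss)
        g <- model_backward(model, fw$cache, ls$dlogits)
        acc_grads <- if (is.null(acc_grads)) g else
          tree_map(`+`, acc_grads, g)
        n_acc <- n_acc + 1L
        if (n_acc >= cfg$batch_size) flush()
      }
      flush()
      val_loss <- mean(vapply(val_inputs, function(v)
        night_loss(model, v, cfg$modalities), numeric(1)), na.rm = TRUE)
      train_hist <- c(train_hist, mean(ep_losses))
      val_hist <- c(val_hist, val_loss)
      if (!quiet) {
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        mean(ep_losses), val_loss))
      }
      plan <- early_stopping_plan(val_hist, cfg$patience)
      if (identical(plan$best_epoch, epoch)) best_params <- model$params
      if (!is.na(plan$stop_epoch)) break
    }
    model$params <- best_params
    list(model = model,
         history = data.frame(epoch = seq_along(val_hist),
                              train_loss = train_hist, val_loss = val_hist),
         best_epoch = early_stopping_plan(val_hist, cfg$patience)$best_epoch)
  })
}

#' Leave-one-subject-out splits
#'
#' One split per participant: that participant is the test subject, the
#' remainder are partitioned into validation (`max(2, ceiling(n/6))`
#' participants, giving the 10/2 train/validation split at 13
#' participants) and training sets, deterministically under `seed`.
#'
#' @param participants Character vector of participant ids.
#' @param seed Integer seed.
#' @param n_val Validation-set size override.
#' @return List of splits: each a list with `test`, `train`, `val`.
#' @export
make_loso_splits <- function(participants, seed = 1L, n_val = NULL) {
  participants <- unique(participants)
  n <- length(participants)
  if (n < 4) stop("need at least 4 participants for LOSO splitting")
  lapply(seq_len(n), function(i) {
    rest <- setdiff(participants, participants[i])
    k <- if (is.null(n_val)) max(2, ceiling(length(rest) / 6)) else n_val
    val <- with_seed(derive_seed(seed, i),
                     sort(sample(rest, k)))
    list(test = participants[i], val = val, train = setdiff(rest, val))
  })
}

#' Run leave-one-subject-out cross-validation
#'
#' For each split, initializes from `base_model` (transfer learning) or
#' from fresh weights, fits with early stopping, and predicts every test
#' night. No test-participant night contributes a gradient (audited).
#'
#' @param inputs List of `model_input` (the cohort, post-preprocessing).
#' @param cfg [train_config()].
#' @param model_cfg [model_config()] used when training from scratch.
#' @param base_model Optional pretrained [build_model()] result.
#' @return List with `predictions` (per-epoch data.frame: participant,
#'   night_label, epoch, truth, prediction), `confusion`, `kappa`,
#'   `accuracy`, and per-split histories.
#' @export
run_loso <- function(inputs, cfg = train_config(),
                     model_cfg = reduced_model_config(),
                     base_model = NULL) {
  pids <- vapply(inputs, function(x) x$participant_id, character(1))
  splits <- make_loso_splits(unique(pids), seed = cfg$seed)
  preds <- list()
  histories <- list()
  for (si in seq_along(splits)) {
    sp <- splits[[si]]
    stopifnot(!(sp$test %in% sp$train), !(sp$test %in% sp$val),
              length(intersect(sp$train, sp$val)) == 0)
    tr <- inputs[pids %in% sp$train]
    va <- inputs[pids %in% sp$val]
    te <- inputs[pids %in% sp$test]
    # id audit: no test night may reach the optimizer
    stopifnot(!any(vapply(c(tr, va), function(x)
      x$participant_id == sp$test, logical(1))))
    model <- if (is.null(base_model)) {
      build_model(model_cfg, seed = derive_seed(cfg$seed, 1000L + si))
    } else base_model
    fcfg <- cfg
    fcfg$seed <- derive_seed(cfg$seed, 2000L + si)
    ft <- fit_model(model, tr, va, fcfg)
    histories[[sp$test]] <- ft$history
    for (inp in te) {
      post <- predict_stages(ft$model, inp, cfg$modalities)
      keep <- which(inp$loss_mask)
      preds[[length(preds) + 1L]] <- data.frame(
        participant_id = inp$participant_id,
        night_label = inp$night_label,
        epoch = keep - 1L,
        truth = as.character(inp$labels)[keep],
        prediction = as.character(post$stages)[keep])
    }
  }
  predictions <- do.call(rbind, preds)
  cm <- confusion(hypnogram(predictions$truth), hypnogram(predictions$prediction))
  list(predictions = predictions, confusion = cm,
       accuracy = accuracy(cm), kappa = cohens_kappa(cm),
       histories = histories)
}
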