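# Neural-network primitives: forward/backward pairs on T x C matrices.
# All layers operate on one sequence at a time (time along rows, channels
# along columns); gradients are accumulated across sequences by the
# training loop. Written against base-R BLAS; no framework dependency.

## ---- parameter initialisation -------------------------------------------

init_conv <- function(k, cin, cout) {
  list(W = array(stats::rnorm(k * cin * cout, sd = sqrt(2 / (k * cin))),
                 dim = c(k, cin, cout)),
       b = numeric(cout))
}

init_dense <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

init_norm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

## ---- conv1d (same zero padding, odd kernel, optional dilation) ----------

conv1d_fwd <- function(x, p, dilation = 1L) {
  list(y = .conv1d_fwd_cpp(x, p$W, p$b, as.integer(dilation)), x = x)
}

conv1d_bwd <- function(dy, cache, p, dilation = 1L) {
  r <- .conv1d_bwd_cpp(cache$x, dy, p$W, as.integer(dilation))
  list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

## ---- normalisation over time (per channel) ------------------------------
# Statistics are computed over the time dimension of the current
# sequence in both training and evaluation (instance-norm semantics;
# deterministic per input, which whole-night single-sequence batching
# makes the natural choice).

norm_time_fwd <- function(x, p, eps = 1e-5) {
  .norm_time_fwd_cpp(x, p$gamma, p$beta, eps)
}

norm_time_bwd <- function(dy, cache, p) {
  r <- .norm_time_bwd_cpp(dy, cache$xhat, cache$inv_sd, p$gamma)
  list(dx = r$dx, grads = list(gamma = as.numeric(r$dgamma),
                               beta = as.numeric(r$dbeta)))
}

## ---- layer norm (per time step over channels) ---------------------------

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  y <- sweep(xhat, 2, p$gamma, `*`)
  y <- sweep(y, 2, p$beta, `+`)
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(dy, cache, p) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, p$gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- relu / maxpool / dense ---------------------------------------------

relu_fwd <- function(x) list(y = x * (x > 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

maxpool2_fwd <- function(x) {
  stopifnot(nrow(x) %% 2 == 0)
  .maxpool2_fwd_cpp(x)
}

maxpool2_bwd <- function(dy, cache) {
  .maxpool2_bwd_cpp(dy, cache$sel)
}

dense_fwd <- function(x, p) list(y = x %*% p$W + rep(p$b, each = nrow(x)), x = x)
dense_bwd <- function(dy, cache, p) {
  list(dx = dy %*% t(p$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

## ---- dropout (inverted; identity in eval mode) --------------------------

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate),
                 nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

## ---- multi-head self-attention ------------------------------------------

attention_fwd <- function(x, p, n_heads) {
  n <- nrow(x)
  d <- ncol(x)
  dh <- d %/% n_heads
  Q <- x %*% p$Wq + rep(p$bq, each = n)
  K <- x %*% p$Wk + rep(p$bk, each = n)
  V <- x %*% p$Wv + rep(p$bv, each = n)
  O <- matrix(0, n, d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    S <- S - apply(S, 1, max)           # row-stable softmax
    E <- exp(S)
    A <- E / rowSums(E)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  Y <- O %*% p$Wo + rep(p$bo, each = n)
  list(y = Y, x = x, Q = Q, K = K, V = V, O = O, A = A_list, n_heads = n_heads)
}

attention_bwd <- function(dy, cache, p) {
  x <- cache$x
  n <- nrow(x)
  d <- ncol(x)
  H <- cache$n_heads
  dh <- d %/% H
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- dy %*% t(p$Wo)
  dQ <- matrix(0, n, d)
  dK <- matrix(0, n, d)
  dV <- matrix(0, n, d)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    # softmax backward (row-wise): dS = A * (dA - rowSums(dA * A))
    dS <- A * (dA - rowSums(dA * A))
    dS <- dS / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dx,
       grads = list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                    Wk = crossprod(x, dK), bk = colSums(dK),
                    Wv = crossprod(x, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

init_attention <- function(d) {
  s <- sqrt(1 / d)
  list(Wq = matrix(stats::rnorm(d * d, sd = s), d, d), bq = numeric(d),
       Wk = matrix(stats::rnorm(d * d, sd = s), d, d), bk = numeric(d),
       Wv = matrix(stats::rnorm(d * d, sd = s), d, d), bv = numeric(d),
       Wo = matrix(stats::rnorm(d * d, sd = s), d, d), bo = numeric(d))
}

## ---- sinusoidal positional encoding -------------------------------------

positional_encoding <- function(n, d) {
  pos <- seq_len(n) - 1
  pe <- matrix(0, n, d)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= d) pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}

## ---- parameter-tree utilities -------------------------------------------

# Recursively apply `f` elementwise over one or more parameter trees with
# identical structure (lists of numeric arrays).
tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

# Sum of f(leaf) over a tree (e.g. parameter counting).
tree_reduce_sum <- function(f, tree) {
  if (is.list(tree)) sum(vapply(tree, function(t) tree_reduce_sum(f, t), numeric(1)))
  else f(tree)
}

zeros_like <- function(tree) tree_map(function(a) a * 0, tree)

# Flatten a parameter tree to a numeric vector and back (gradient checks,
# checkpoint serialization).
tree_flatten <- function(tree) unlist(tree, use.names = FALSE)

tree_unflatten <- function(skeleton, vec) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) {
      lapply(node, walk)
    } else {
      n <- length(node)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      attributes(out) <- attributes(node)
      out
    }
  }
  out <- walk(skeleton)
  stopifnot(pos == length(vec))
  out
}
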