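# Minimal dense-network machinery: explicit forward caches, hand-written
# backprop and ADAM. All layers are plain matrix products; activations are
# ReLU (encoder) or ELU (decoder / inverse net).

act_fun <- function(name) {
  switch(name,
    relu = list(
      f = function(x) { x[x < 0] <- 0; x },
      df = function(x, y) (x > 0) * 1),
    elu = list(
      f = function(x) { n <- x < 0; x[n] <- exp(x[n]) - 1; x },
      df = function(x, y) { d <- matrix(1, nrow(x), ncol(x)); n <- x < 0
                            d[n] <- y[n] + 1; d }),
    stop("unknown activation ", name))
}

# dims: c(n_in, h1, ..., n_out). Final layer optionally zero-initialized so
# residual architectures start as the identity.
mlp_new <- function(dims, activation = "elu", final_zero = TRUE,
                    seed = 1) {
  rng <- local_rng(seed)
  L <- length(dims) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    sdv <- sqrt(2 / dims[l])
    W[[l]] <- matrix(rng$rnorm(dims[l] * dims[l + 1], 0, sdv),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
    if (final_zero && l == L) W[[l]][] <- 0
  }
  list(W = W, b = b, dims = dims, activation = activation)
}

mlp_forward <- function(net, X, keep_cache = TRUE) {
  L <- length(net$W)
  act <- act_fun(net$activation)
  Z <- vector("list", L); A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    z <- A[[l]] %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], "+")
    if (l < L) {
      Z[[l]] <- z
      A[[l + 1]] <- act$f(z)
    } else A[[l + 1]] <- z
  }
  out <- A[[L + 1]]
  if (keep_cache) list(out = out, A = A, Z = Z) else list(out = out)
}

# dOut: gradient wrt network output. Returns parameter gradients and the
# gradient wrt the input rows.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  act <- act_fun(net$activation)
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- dOut
  for (l in L:1) {
    dW[[l]] <- crossprod(cache$A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, net$W[[l]])
    if (l > 1) dZ <- dA * act$df(cache$Z[[l - 1]], cache$A[[l]])
  }
  list(dW = dW, db = db, dX = dA)
}

mlp_params <- function(net) c(net$W, net$b)

mlp_set_params <- function(net, params) {
  L <- length(net$W)
  net$W <- params[seq_len(L)]
  net$b <- params[L + seq_len(L)]
  net
}

mlp_grad_list <- function(bk) c(bk$dW, bk$db)

param_norm <- function(params) sqrt(sum(vapply(params, function(p)
  sum(p^2), 0)))

# --- ADAM -------------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g * g
    params[[i]] <- params[[i]] - state$lr * (state$m[[i]] / c1) /
      (sqrt(state$v[[i]] / c2) + state$eps)
  }
  list(state = state, params = params)
}

# --- positional encoding ----------------------------------------------

#' Positional encoding of 3D coordinates
#'
#' Lifts coordinates (in normalized box units, roughly `[-1, 1]`) to
#' `[sin(2^m pi x_d), cos(2^m pi x_d)]` for `m = 0..n_freq-1` and
#' `d = 1..3`, with the raw coordinates appended, giving
#' `6 * n_freq + 3` features (63 for the default ten frequencies).
#'
#' @param x M x 3 matrix (or length-3 vector) of normalized coordinates.
#' @param n_freq number of frequency octaves (default 10).
#' @return M x (6 n_freq + 3) feature matrix.
#' @export
positional_encode <- function(x, n_freq = 10) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  m <- nrow(x)
  out <- matrix(0, m, 6 * n_freq + 3)
  for (f in seq_len(n_freq)) {
    arg <- (2^(f - 1) * pi) * x
    out[, (f - 1) * 6 + 1:3] <- sin(arg)
    out[, (f - 1) * 6 + 4:6] <- cos(arg)
  }
  out[, 6 * n_freq + 1:3] <- x
  out
}

# Chain rule through the positional encoding: given dL/d(features) (M x F),
# return dL/dx (M x 3).
positional_encode_backward <- function(x, dF, n_freq = 10) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  dX <- dF[, 6 * n_freq + 1:3, drop = FALSE]
  for (f in seq_len(n_freq)) {
    w <- 2^(f - 1) * pi
    arg <- w * x
    dX <- dX + dF[, (f - 1) * 6 + 1:3, drop = FALSE] * (w * cos(arg)) -
      dF[, (f - 1) * 6 + 4:6, drop = FALSE] * (w * sin(arg))
  }
  dX
}
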