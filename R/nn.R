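# Minimal neural-network engine for the temporal and spatial gait networks.
#
# Activations travel between layers as dense (channels x time*batch)
# matrices plus a `tb = c(T, B)` shape descriptor; because R arrays are
# column-major, a (C, T, B) tensor and a (C, T*B) matrix share the same
# linear layout, so reshapes at the API boundary are single copies and the
# layer internals never convert. Convolutions are evaluated as one BLAS
# matrix product per kernel tap on a zero-padded gather of the input;
# backward passes are written by hand layer by layer. Nothing here depends
# on an external autodiff framework.

ctb <- function(x) {
  # promote a single (C x T) matrix to a (C, T, 1) batch
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  list(m = x, tb = c(d[2], d[3]))
}

as_arr <- function(m, tb) {
  dim(m) <- c(nrow(m), tb[1], tb[2])
  m
}

tap_index <- function(T_out, Tp, B, offset) {
  # 1-based columns of the flattened padded input matrix hit by one tap
  as.vector(outer(seq_len(T_out) + offset, (seq_len(B) - 1L) * Tp, `+`))
}

## ---- layers ----------------------------------------------------------------

layer_conv1d <- function(in_ch, out_ch, kernel, dilation = 1L,
                         pad = c(0L, 0L)) {
  fan_in <- in_ch * kernel
  W <- array(stats::rnorm(out_ch * in_ch * kernel, sd = sqrt(2 / fan_in)),
             c(out_ch, in_ch, kernel))
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       dilation = as.integer(dilation), pad = as.integer(pad),
       params = list(W = W, b = numeric(out_ch)))
}

conv1d_forward <- function(layer, m, tb) {
  T_in <- tb[1]; B <- tb[2]; Cin <- layer$in_ch
  pl <- layer$pad[1]; pr <- layer$pad[2]
  Tp <- T_in + pl + pr
  T_out <- Tp - (layer$kernel - 1L) * layer$dilation
  dest <- tap_index(T_in, Tp, B, pl)
  Xp <- matrix(0, Cin, Tp * B)
  Xp[, dest] <- m
  W <- layer$params$W
  Y <- matrix(layer$params$b, layer$out_ch, T_out * B)
  idx <- vector("list", layer$kernel)
  for (k in seq_len(layer$kernel)) {
    idx[[k]] <- tap_index(T_out, Tp, B, (k - 1L) * layer$dilation)
    Y <- Y + matrix(W[, , k], layer$out_ch, Cin) %*%
      Xp[, idx[[k]], drop = FALSE]
  }
  list(y = Y, tb = c(T_out, B),
       cache = list(Xp = Xp, idx = idx, dest = dest, Tp = Tp, B = B))
}

conv1d_backward <- function(layer, dY, cache) {
  W <- layer$params$W
  dW <- array(0, dim(W))
  dXp <- matrix(0, layer$in_ch, cache$Tp * cache$B)
  for (k in seq_len(layer$kernel)) {
    cols <- cache$idx[[k]]
    Xs <- cache$Xp[, cols, drop = FALSE]
    dW[, , k] <- tcrossprod(dY, Xs)
    dXp[, cols] <- dXp[, cols] +
      crossprod(matrix(W[, , k], layer$out_ch, layer$in_ch), dY)
  }
  list(dx = dXp[, cache$dest, drop = FALSE],
       grads = list(W = dW, b = rowSums(dY)))
}

layer_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       buffers = list(running_mean = numeric(ch), running_var = rep(1, ch)))
}

batchnorm_forward <- function(layer, m, training) {
  N <- ncol(m)
  if (training) {
    mu <- rowMeans(m)
    v <- pmax(rowMeans(m * m) - mu * mu, 0)
  } else {
    mu <- layer$buffers$running_mean
    v <- layer$buffers$running_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- (m - mu) * inv
  y <- layer$params$gamma * xhat + layer$params$beta
  buf_update <- NULL
  if (training) {
    mom <- layer$momentum
    v_unb <- if (N > 1) v * N / (N - 1) else v
    buf_update <- list(
      running_mean = (1 - mom) * layer$buffers$running_mean + mom * mu,
      running_var = (1 - mom) * layer$buffers$running_var + mom * v_unb)
  }
  list(y = y, cache = list(xhat = xhat, inv = inv, N = N,
                           buf_update = buf_update))
}

batchnorm_backward <- function(layer, dY, cache) {
  g <- layer$params$gamma
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  N <- cache$N
  # using rowSums(dxhat) = dbeta*g and rowSums(dxhat*xhat) = dgamma*g
  dX <- (cache$inv / N) * (N * dY * g - dbeta * g - cache$xhat * dgamma * g)
  list(dx = dX, grads = list(gamma = dgamma, beta = dbeta))
}

layer_relu <- function() list(type = "relu", params = list())

layer_dropout <- function(p) list(type = "dropout", p = p, params = list())

layer_chomp <- function(n) list(type = "chomp", n = as.integer(n),
                                params = list())

layer_forward <- function(layer, m, tb, training) {
  switch(layer$type,
    conv1d = conv1d_forward(layer, m, tb),
    batchnorm = c(batchnorm_forward(layer, m, training), list(tb = tb)),
    relu = list(y = pmax(m, 0), tb = tb, cache = m > 0),
    dropout = {
      if (training && layer$p > 0) {
        mask <- matrix((stats::runif(length(m)) >= layer$p) / (1 - layer$p),
                       nrow(m))
        list(y = m * mask, tb = tb, cache = mask)
      } else list(y = m, tb = tb, cache = NULL)
    },
    chomp = {
      T_out <- tb[1] - layer$n
      keep <- tap_index(T_out, tb[1], tb[2], 0L)
      list(y = m[, keep, drop = FALSE], tb = c(T_out, tb[2]),
           cache = list(keep = keep, n_in = ncol(m)))
    },
    stop_mear(paste("unknown layer type", layer$type), "mear_config_error"))
}

layer_backward <- function(layer, dY, cache) {
  switch(layer$type,
    conv1d = conv1d_backward(layer, dY, cache),
    batchnorm = batchnorm_backward(layer, dY, cache),
    relu = list(dx = dY * cache, grads = list()),
    dropout = list(dx = if (is.null(cache)) dY else dY * cache,
                   grads = list()),
    chomp = {
      dx <- matrix(0, nrow(dY), cache$n_in)
      dx[, cache$keep] <- dY
      list(dx = dx, grads = list())
    })
}

seq_forward_mat <- function(layers, m, tb, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    out <- layer_forward(layers[[i]], m, tb, training)
    m <- out$y
    tb <- out$tb
    caches[i] <- list(out$cache)  # keeps NULL caches in place
  }
  list(y = m, tb = tb, caches = caches)
}

seq_backward_mat <- function(layers, caches, dm) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    out <- layer_backward(layers[[i]], dm, caches[[i]])
    dm <- out$dx
    grads[[i]] <- out$grads
  }
  list(dx = dm, grads = grads)
}

# x: (C, T, B) array (or C x T matrix). Output y is returned as an array;
# caches keep the flat-layout intermediates for seq_backward.
seq_forward <- function(layers, x, training = FALSE) {
  s <- as_mat(ctb(x))
  out <- seq_forward_mat(layers, s$m, s$tb, training)
  list(y = as_arr(out$y, out$tb), caches = out$caches, tb = out$tb)
}

seq_backward <- function(layers, caches, dy) {
  s <- as_mat(ctb(dy))
  seq_backward_mat(layers, caches, s$m)
}

# fold freshly computed batch-norm running statistics back into the layers
seq_update_buffers <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (!is.list(caches[[i]])) next
    upd <- caches[[i]]$buf_update
    if (!is.null(upd)) layers[[i]]$buffers <- upd
  }
  layers
}

## ---- parameter plumbing ----------------------------------------------------

params_get <- function(layers) lapply(layers, function(l) l$params)

params_set <- function(layers, params) {
  for (i in seq_along(layers)) layers[[i]]$params <- params[[i]]
  layers
}

## ---- optimizer -------------------------------------------------------------
# Parameters live in arbitrarily nested lists whose leaves are numeric
# arrays; gradients mirror the structure exactly. Adam recurses over the
# tree, so the same optimizer serves the sequential temporal network and
# the residual spatial network.

tree_zero <- function(x) {
  if (is.numeric(x)) return(x * 0)
  lapply(x, tree_zero)
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      return(list(p = p, m = m, v = v))
    }
    for (i in seq_along(p)) {
      r <- rec(p[[i]], g[[i]], m[[i]], v[[i]])
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

## ---- losses ----------------------------------------------------------------

bce_with_logits <- function(z, y) {
  if (!is.null(dim(y)) && !identical(dim(y), dim(z))) dim(y) <- dim(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  dz <- (stats::plogis(z) - y) / length(z)
  list(loss = loss, dz = dz)
}

mse_loss <- function(pred, y) {
  r <- pred - y
  list(loss = mean(r * r), dpred = 2 * r / length(r))
}

sigmoid <- function(x) stats::plogis(x)
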