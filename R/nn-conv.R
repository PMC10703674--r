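# 3D convolutional network primitives. Arrays are (x, y, z, channel,
# batch); convolution weights are (out_channels) x (k^3 * in_channels)
# matrices matching the im2col row order of the C++ kernels. Convolutions
# carry no bias (batch norm supplies the shift).

conv_init <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
}

conv_fw <- function(x, w, k, s, pad) conv3d_forward_cpp(x, w, k, s, pad)
conv_bw <- function(x, w, dy, k, s, pad) conv3d_backward_cpp(x, w, dy, k, s, pad)

bn_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
bn_state_init <- function(c) list(mean = rep(0, c), var = rep(1, c))

# Batch norm over (space x batch) per channel.
bn_fw <- function(x, par, state, training, momentum = 0.1, eps = 1e-5) {
  dm <- dim(x)
  C <- dm[4]; B <- dm[5]
  spn <- prod(dm[1:3])
  m <- matrix(x, nrow = spn)
  idx <- rep(seq_len(C), B)
  if (training) {
    cm <- colMeans(m)
    mean_c <- rowMeans(matrix(cm, C, B))
    vm <- colMeans(m^2)
    var_c <- rowMeans(matrix(vm, C, B)) - mean_c^2
    state$mean <- (1 - momentum) * state$mean + momentum * mean_c
    state$var <- (1 - momentum) * state$var + momentum * var_c
  } else {
    mean_c <- state$mean
    var_c <- state$var
  }
  sc <- 1 / sqrt(var_c + eps)
  xhat <- sweep(sweep(m, 2, mean_c[idx]), 2, sc[idx], "*")
  y <- sweep(sweep(xhat, 2, par$gamma[idx], "*"), 2, par$beta[idx], "+")
  dim(y) <- dm
  list(y = y, state = state,
       cache = list(xhat = xhat, sc = sc, idx = idx, dm = dm))
}

bn_bw <- function(dy, par, cache) {
  dm <- cache$dm
  C <- dm[4]; B <- dm[5]
  spn <- prod(dm[1:3])
  dmat <- matrix(dy, nrow = spn)
  xhat <- cache$xhat
  n_tot <- spn * B
  sum_by_c <- function(v) rowSums(matrix(v, C, B))
  dgamma <- sum_by_c(colSums(dmat * xhat))
  dbeta <- sum_by_c(colSums(dmat))
  g <- par$gamma[cache$idx]
  dxhat <- sweep(dmat, 2, g, "*")
  s1 <- sum_by_c(colSums(dxhat))
  s2 <- sum_by_c(colSums(dxhat * xhat))
  dx <- sweep(
    dxhat - sweep(xhat, 2, (s2 / n_tot)[cache$idx], "*"),
    2, (s1 / n_tot)[cache$idx]) |>
    sweep(2, cache$sc[cache$idx], "*")
  dim(dx) <- dm
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bw <- function(dy, cache) dy * cache

global_pool_fw <- function(x) {
  dm <- dim(x)
  spn <- prod(dm[1:3])
  f <- t(matrix(colMeans(matrix(x, nrow = spn)), dm[4], dm[5]))  # B x C
  list(y = f, cache = dm)
}

global_pool_bw <- function(df, dm) {
  spn <- prod(dm[1:3])
  per <- t(df) / spn                       # C x B
  dx <- array(rep(as.numeric(per), each = spn), dim = dm)
  dx
}

dense_init <- function(nin, nout) {
  list(W = he_mat(nin, nout), b = numeric(nout))
}

dense_fw <- function(x, par) {
  list(y = sweep(x %*% par$W, 2, par$b, "+"), cache = x)
}

dense_bw <- function(dy, par, cache) {
  list(dx = dy %*% t(par$W), dW = t(cache) %*% dy, db = colSums(dy))
}

# Multi-layer dense head: ReLU between layers, linear final output.
mlp_head_init <- function(d_in, widths) {
  sizes <- c(d_in, widths)
  purrr::map(seq_len(length(widths)), function(i)
    dense_init(sizes[i], sizes[i + 1]))
}

mlp_head_fw <- function(x, layers) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- dense_fw(x, layers[[i]])
    caches[[i]] <- list(dense = fw$cache)
    x <- fw$y
    if (i < length(layers)) {
      rl <- relu_fw(x)
      caches[[i]]$relu <- rl$cache
      x <- rl$y
    }
  }
  list(y = x, caches = caches)
}

mlp_head_bw <- function(dy, layers, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i < length(layers)) dy <- relu_bw(dy, caches[[i]]$relu)
    bw <- dense_bw(dy, layers[[i]], caches[[i]]$dense)
    grads[[i]] <- list(W = bw$dW, b = bw$db)
    dy <- bw$dx
  }
  list(dx = dy, grads = grads)
}
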