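# Minimal dense-network engine: an input projection followed by shallow
# residual fully-connected blocks, trained with Adam. Used by the
# two-module residual classifier ("ResNet-2") and by the SNGP head's
# spectrally normalized trunk. Inputs are row-example matrices.

he_mat <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

trunk_init <- function(d_in, width, n_blocks = 2) {
  params <- list(W_in = he_mat(d_in, width), b_in = numeric(width))
  for (k in seq_len(n_blocks)) {
    params[[paste0("W", k, "a")]] <- he_mat(width, width)
    params[[paste0("b", k, "a")]] <- numeric(width)
    params[[paste0("W", k, "b")]] <- he_mat(width, width) * 0.1
    params[[paste0("b", k, "b")]] <- numeric(width)
  }
  params
}

# h0 = relu(X W_in + b); block k: h <- h + W_b relu(h W_a + b_a) + b_b
trunk_forward <- function(params, X, n_blocks = 2) {
  pre_in <- sweep(X %*% params$W_in, 2, params$b_in, "+")
  h <- pmax(pre_in, 0)
  caches <- list(X = X, pre_in = pre_in, hs = list())
  for (k in seq_len(n_blocks)) {
    pre_a <- sweep(h %*% params[[paste0("W", k, "a")]], 2,
                   params[[paste0("b", k, "a")]], "+")
    act_a <- pmax(pre_a, 0)
    delta <- sweep(act_a %*% params[[paste0("W", k, "b")]], 2,
                   params[[paste0("b", k, "b")]], "+")
    caches$hs[[k]] <- list(h_in = h, pre_a = pre_a, act_a = act_a)
    h <- h + delta
  }
  list(h = h, caches = caches)
}

trunk_backward <- function(params, caches, dH, n_blocks = 2) {
  grads <- list()
  for (k in rev(seq_len(n_blocks))) {
    cc <- caches$hs[[k]]
    grads[[paste0("b", k, "b")]] <- colSums(dH)
    grads[[paste0("W", k, "b")]] <- t(cc$act_a) %*% dH
    d_act_a <- dH %*% t(params[[paste0("W", k, "b")]])
    d_pre_a <- d_act_a * (cc$pre_a > 0)
    grads[[paste0("b", k, "a")]] <- colSums(d_pre_a)
    grads[[paste0("W", k, "a")]] <- t(cc$h_in) %*% d_pre_a
    dH <- dH + d_pre_a %*% t(params[[paste0("W", k, "a")]])
  }
  d_pre_in <- dH * (caches$pre_in > 0)
  grads$b_in <- colSums(d_pre_in)
  grads$W_in <- t(caches$X) %*% d_pre_in
  grads
}

adam_state <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Power-iteration estimate of the top singular value; u persists across
# calls for fast convergence.
spectral_sigma <- function(W, u, n_iter = 1) {
  for (i in seq_len(n_iter)) {
    v <- as.numeric(t(W) %*% u); v <- v / max(sqrt(sum(v^2)), 1e-12)
    u <- as.numeric(W %*% v); u <- u / max(sqrt(sum(u^2)), 1e-12)
  }
  sigma <- as.numeric(t(u) %*% W %*% v)
  list(sigma = sigma, u = u)
}

# Rescale hidden weight matrices whose spectral norm exceeds the bound.
apply_spectral_norm <- function(params, sn_state, bound) {
  for (nm in names(sn_state)) {
    est <- spectral_sigma(params[[nm]], sn_state[[nm]])
    sn_state[[nm]] <- est$u
    if (est$sigma > bound) {
      params[[nm]] <- params[[nm]] * (bound / est$sigma)
    }
  }
  list(params = params, sn_state = sn_state)
}

cross_entropy_grad <- function(logits, y_onehot) {
  p <- softmax_rows(logits)
  loss <- -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
  list(loss = loss, dlogits = (p - y_onehot) / nrow(logits))
}
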