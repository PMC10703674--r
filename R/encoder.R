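#' Encoder architecture configuration
#'
#' Describes the embedding network: a residual convolutional trunk with 3D
#' convolutions (ResNet-18 layout in the reference configuration), global
#' average pooling, a bottleneck stack of dense layers ending at the
#' embedding dimension (64), and a projection stack ending at the
#' contrastive output dimension (16) that is used only during training.
#'
#' @param view_size Input cube side in voxels.
#' @param in_channels Input channels (1 for masked intensity).
#' @param stem_channels,stem_kernel,stem_stride Stem convolution.
#' @param stem_pool Apply a 3x3x3 stride-2 max pool after the stem.
#' @param stage_widths Channel width per residual stage.
#' @param blocks_per_stage Residual blocks per stage.
#' @param stage_strides Stride of the first block of each stage.
#' @param bottleneck_widths Dense widths after pooling; last entry is the
#'   embedding dimension.
#' @param projection_widths Dense widths of the training-only projection
#'   head; last entry is the contrastive output dimension.
#' @return A `segclr_encoder_config`.
#' @export
encoder_config <- function(view_size = 129,
                           in_channels = 1,
                           stem_channels = 64,
                           stem_kernel = 7,
                           stem_stride = 2,
                           stem_pool = TRUE,
                           stage_widths = c(64, 128, 256, 512),
                           blocks_per_stage = c(2, 2, 2, 2),
                           stage_strides = c(1, 2, 2, 2),
                           bottleneck_widths = c(512, 512, 64),
                           projection_widths = c(112, 96, 16)) {
  stopifnot(length(stage_widths) == length(blocks_per_stage),
            length(stage_widths) == length(stage_strides),
            all(stage_widths > 0), all(bottleneck_widths > 0),
            all(projection_widths > 0))
  structure(list(view_size = view_size, in_channels = in_channels,
                 stem_channels = stem_channels, stem_kernel = stem_kernel,
                 stem_stride = stem_stride, stem_pool = stem_pool,
                 stage_widths = stage_widths,
                 blocks_per_stage = blocks_per_stage,
                 stage_strides = stage_strides,
                 bottleneck_widths = bottleneck_widths,
                 projection_widths = projection_widths,
                 embedding_dim = bottleneck_widths[length(bottleneck_widths)],
                 projection_dim = projection_widths[length(projection_widths)]),
            class = "segclr_encoder_config")
}

#' Reference encoder configuration
#'
#' The full-scale configuration: a 3D ResNet-18 trunk (7^3 stem, four
#' stages of two basic blocks at widths 64/128/256/512, batch norm, 1^3
#' projection shortcuts), bottleneck 512-512-64 and projection 112-96-16.
#' Its trainable parameter count is 33,737,824.
#' @return A `segclr_encoder_config`.
#' @export
encoder_config_full <- function() encoder_config()

#' Toy encoder configuration for desk-scale experiments
#'
#' A small trunk for 33-voxel views: 3^3 stem (stride 2), three stages of
#' one basic block at widths 8/16/32, bottleneck 32-32-64, projection
#' 32-32-16. Keeps the exact architecture family of the reference
#' configuration at a size trainable in minutes on one CPU.
#' @param view_size Input cube side (default 33).
#' @return A `segclr_encoder_config`.
#' @export
encoder_config_toy <- function(view_size = 33) {
  encoder_config(view_size = view_size, stem_channels = 8, stem_kernel = 3,
                 stem_stride = 2, stem_pool = FALSE,
                 stage_widths = c(8, 16, 32), blocks_per_stage = c(1, 1, 1),
                 stage_strides = c(2, 2, 2),
                 bottleneck_widths = c(32, 32, 64),
                 projection_widths = c(32, 32, 16))
}

#' Count trainable parameters of an encoder configuration
#'
#' Sums convolution weights (no biases; batch norm supplies the shift),
#' batch-norm scale and shift parameters, and dense weights and biases of
#' the bottleneck and projection stacks.
#'
#' @param config A [encoder_config()].
#' @param include_projection Include the training-only projection head.
#' @return Integer parameter count.
#' @export
count_parameters <- function(config, include_projection = TRUE) {
  n <- 0
  conv <- function(k, cin, cout) k^3 * cin * cout
  bn <- function(c) 2 * c
  n <- n + conv(config$stem_kernel, config$in_channels,
                config$stem_channels) + bn(config$stem_channels)
  cin <- config$stem_channels
  for (s in seq_along(config$stage_widths)) {
    w <- config$stage_widths[s]
    for (b in seq_len(config$blocks_per_stage[s])) {
      n <- n + conv(3, cin, w) + bn(w) + conv(3, w, w) + bn(w)
      if (b == 1 && (cin != w || config$stage_strides[s] != 1)) {
        n <- n + conv(1, cin, w) + bn(w)
      }
      cin <- w
    }
  }
  dense <- function(i, o) i * o + o
  sizes <- c(cin, config$bottleneck_widths)
  for (i in seq_len(length(config$bottleneck_widths))) {
    n <- n + dense(sizes[i], sizes[i + 1])
  }
  if (include_projection) {
    sizes <- c(config$embedding_dim, config$projection_widths)
    for (i in seq_len(length(config$projection_widths))) {
      n <- n + dense(sizes[i], sizes[i + 1])
    }
  }
  as.integer(n)
}

#' Build (initialize) an encoder
#'
#' Allocates He-initialized weights for the configured trunk, bottleneck
#' and projection head, plus batch-norm running statistics.
#'
#' @param config A [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `segclr_encoder` with fields `config`, `params`, `state`,
#'   `n_params`, `step`.
#' @export
build_encoder <- function(config, seed = 1L) {
  set.seed(seed)
  params <- list()
  state <- list()
  params$stem <- list(w = conv_init(config$stem_kernel, config$in_channels,
                                    config$stem_channels),
                      bn = bn_init(config$stem_channels))
  state$stem_bn <- bn_state_init(config$stem_channels)
  cin <- config$stem_channels
  params$stages <- list()
  state$stages <- list()
  for (s in seq_along(config$stage_widths)) {
    w <- config$stage_widths[s]
    blocks <- list()
    bstate <- list()
    for (b in seq_len(config$blocks_per_stage[s])) {
      stride <- if (b == 1) config$stage_strides[s] else 1
      blk <- list(conv1 = conv_init(3, cin, w), bn1 = bn_init(w),
                  conv2 = conv_init(3, w, w), bn2 = bn_init(w),
                  stride = stride)
      bst <- list(bn1 = bn_state_init(w), bn2 = bn_state_init(w))
      if (b == 1 && (cin != w || stride != 1)) {
        blk$short_w <- conv_init(1, cin, w)
        blk$short_bn <- bn_init(w)
        bst$short_bn <- bn_state_init(w)
      }
      blocks[[b]] <- blk
      bstate[[b]] <- bst
      cin <- w
    }
    params$stages[[s]] <- blocks
    state$stages[[s]] <- bstate
  }
  params$bottleneck <- mlp_head_init(cin, config$bottleneck_widths)
  params$projection <- mlp_head_init(config$embedding_dim,
                                     config$projection_widths)
  enc <- structure(list(config = config, params = params, state = state,
                        step = 0L),
                   class = "segclr_encoder")
  enc$n_params <- count_encoder_params(enc)
  enc
}

# Count from the actually allocated arrays (cross-check of
# count_parameters()).
count_encoder_params <- function(enc, include_projection = TRUE) {
  n <- length(enc$params$stem$w) + length(enc$params$stem$bn$gamma) +
    length(enc$params$stem$bn$beta)
  for (stage in enc$params$stages) for (blk in stage) {
    n <- n + length(blk$conv1) + length(blk$conv2) +
      2 * (length(blk$bn1$gamma) + length(blk$bn2$gamma))
    if (!is.null(blk$short_w)) {
      n <- n + length(blk$short_w) + 2 * length(blk$short_bn$gamma)
    }
  }
  heads <- enc$params$bottleneck
  if (include_projection) heads <- c(heads, enc$params$projection)
  for (l in heads) n <- n + length(l$W) + length(l$b)
  as.integer(n)
}

#' @export
print.segclr_encoder <- function(x, ...) {
  cat(sprintf(paste0("<segclr_encoder> view %d^3, %s-stage trunk, ",
                     "%d-d embedding, %s trainable parameters (step %d)\n"),
              x$config$view_size, length(x$config$stage_widths),
              x$config$embedding_dim,
              format(x$n_params, big.mark = ","), x$step))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

block_fw <- function(x, blk, bst, training) {
  cache <- list()
  c1 <- conv_fw(x, blk$conv1, 3, blk$stride, 1)
  b1 <- bn_fw(c1, blk$bn1, bst$bn1, training)
  bst$bn1 <- b1$state
  r1 <- relu_fw(b1$y)
  c2 <- conv_fw(r1$y, blk$conv2, 3, 1, 1)
  b2 <- bn_fw(c2, blk$bn2, bst$bn2, training)
  bst$bn2 <- b2$state
  if (!is.null(blk$short_w)) {
    sc <- conv_fw(x, blk$short_w, 1, blk$stride, 0)
    sb <- bn_fw(sc, blk$short_bn, bst$short_bn, training)
    bst$short_bn <- sb$state
    shortcut <- sb$y
    cache$short_in <- x
    cache$short_conv <- sc
    cache$short_bn <- sb$cache
  } else {
    shortcut <- x
  }
  ro <- relu_fw(b2$y + shortcut)
  cache$x <- x; cache$c1 <- c1; cache$bn1 <- b1$cache; cache$r1 <- r1$cache
  cache$r1y <- r1$y; cache$c2in <- r1$y; cache$bn2 <- b2$cache
  cache$ro <- ro$cache
  list(y = ro$y, state = bst, cache = cache)
}

block_bw <- function(dy, blk, cache) {
  grads <- list()
  d <- relu_bw(dy, cache$ro)
  # main branch
  db2 <- bn_bw(d, blk$bn2, cache$bn2)
  grads$bn2 <- list(dgamma = db2$dgamma, dbeta = db2$dbeta)
  dc2 <- conv_bw(cache$c2in, blk$conv2, db2$dx, 3, 1, 1)
  grads$conv2 <- dc2$dw
  dr1 <- relu_bw(dc2$dx, cache$r1)
  db1 <- bn_bw(dr1, blk$bn1, cache$bn1)
  grads$bn1 <- list(dgamma = db1$dgamma, dbeta = db1$dbeta)
  dc1 <- conv_bw(cache$x, blk$conv1, db1$dx, 3, blk$stride, 1)
  grads$conv1 <- dc1$dw
  dx <- dc1$dx
  # shortcut branch
  if (!is.null(blk$short_w)) {
    dsb <- bn_bw(d, blk$short_bn, cache$short_bn)
    grads$short_bn <- list(dgamma = dsb$dgamma, dbeta = dsb$dbeta)
    dsc <- conv_bw(cache$short_in, blk$short_w, dsb$dx, 1, blk$stride, 0)
    grads$short_w <- dsc$dw
    dx <- dx + dsc$dx
  } else {
    dx <- dx + d
  }
  list(dx = dx, grads = grads)
}

trunk_fw_conv <- function(enc, x, training) {
  cfg <- enc$config
  cache <- list()
  st <- conv_fw(x, enc$params$stem$w, cfg$stem_kernel, cfg$stem_stride,
                (cfg$stem_kernel - 1) / 2)
  bn <- bn_fw(st, enc$params$stem$bn, enc$state$stem_bn, training)
  enc$state$stem_bn <- bn$state
  rl <- relu_fw(bn$y)
  h <- rl$y
  cache$stem <- list(x = x, conv = st, bn = bn$cache, relu = rl$cache)
  if (cfg$stem_pool) {
    mp <- maxpool3d_forward_cpp(h, 3L, 2L)
    cache$pool <- list(argmax = mp$argmax, in_dim = dim(h))
    h <- mp$y
  }
  cache$blocks <- list()
  for (s in seq_along(enc$params$stages)) {
    cache$blocks[[s]] <- list()
    for (b in seq_along(enc$params$stages[[s]])) {
      bf <- block_fw(h, enc$params$stages[[s]][[b]],
                     enc$state$stages[[s]][[b]], training)
      enc$state$stages[[s]][[b]] <- bf$state
      cache$blocks[[s]][[b]] <- bf$cache
      h <- bf$y
    }
  }
  gp <- global_pool_fw(h)
  cache$gap_dim <- gp$cache
  list(features = gp$y, cache = cache, enc = enc)
}

trunk_bw_conv <- function(enc, cache, dfeat) {
  grads <- list(stages = list())
  dh <- global_pool_bw(dfeat, cache$gap_dim)
  for (s in rev(seq_along(enc$params$stages))) {
    grads$stages[[s]] <- list()
    for (b in rev(seq_along(enc$params$stages[[s]]))) {
      bb <- block_bw(dh, enc$params$stages[[s]][[b]], cache$blocks[[s]][[b]])
      grads$stages[[s]][[b]] <- bb$grads
      dh <- bb$dx
    }
  }
  if (!is.null(cache$pool)) {
    dh <- maxpool3d_backward_cpp(dh, cache$pool$argmax,
                                 as.integer(cache$pool$in_dim))
  }
  dr <- relu_bw(dh, cache$stem$relu)
  dbn <- bn_bw(dr, enc$params$stem$bn, cache$stem$bn)
  grads$stem_bn <- list(dgamma = dbn$dgamma, dbeta = dbn$dbeta)
  cfg <- enc$config
  dcv <- conv_bw(cache$stem$x, enc$params$stem$w, dbn$dx, cfg$stem_kernel,
                 cfg$stem_stride, (cfg$stem_kernel - 1) / 2)
  grads$stem_w <- dcv$dw
  grads
}

# Full forward: returns embeddings (B x 64) and projections (B x 16).
encoder_fw <- function(enc, x, training = FALSE, project = TRUE) {
  tf <- trunk_fw_conv(enc, x, training)
  bf <- mlp_head_fw(tf$features, enc$params$bottleneck)
  out <- list(enc = tf$enc, embedding = bf$y,
              cache = list(trunk = tf$cache, bottleneck = bf$caches,
                           features = tf$features))
  if (project) {
    pf <- mlp_head_fw(bf$y, enc$params$projection)
    out$projection <- pf$y
    out$cache$projection <- pf$caches
  }
  out
}

# Backward from head gradients; returns the full gradient tree.
encoder_bw <- function(enc, fw, d_embedding = NULL, d_projection = NULL) {
  grads <- list()
  dE <- if (is.null(d_embedding)) 0 else d_embedding
  if (!is.null(d_projection)) {
    pb <- mlp_head_bw(d_projection, enc$params$projection,
                      fw$cache$projection)
    grads$projection <- pb$grads
    dE <- dE + pb$dx
  }
  bb <- mlp_head_bw(dE, enc$params$bottleneck, fw$cache$bottleneck)
  grads$bottleneck <- bb$grads
  grads$trunk <- trunk_bw_conv(enc, fw$cache$trunk, bb$dx)
  grads
}
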