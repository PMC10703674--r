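# Contrastive training loop, refinement, and embedding inference.

# Momentum-SGD schedule: learning rate scaled linearly to the number of
# examples per batch (relative to the 1,024-example reference batch),
# with a short linear warmup and cosine decay.
lr_at <- function(step, total_steps, base_lr, batch_examples,
                  warmup_frac = 0.05) {
  scaled <- base_lr * batch_examples / 1024
  warm <- max(1, ceiling(warmup_frac * total_steps))
  if (step <= warm) return(scaled * step / warm)
  frac <- (step - warm) / max(1, total_steps - warm)
  scaled * 0.5 * (1 + cos(pi * min(frac, 1)))
}

# Flatten-free SGD-with-momentum update over the encoder gradient tree.
sgd_update_encoder <- function(enc, grads, vel, lr, momentum = 0.9) {
  upd <- function(p, g, v) {
    v <- momentum * v + g
    list(p = p - lr * v, v = v)
  }
  if (is.null(vel)) vel <- list()
  gv <- function(key, default) vel[[key]] %||% default
  # stem
  u <- upd(enc$params$stem$w, grads$trunk$stem_w, gv("stem_w", 0))
  enc$params$stem$w <- u$p; vel[["stem_w"]] <- u$v
  u <- upd(enc$params$stem$bn$gamma, grads$trunk$stem_bn$dgamma,
           gv("stem_bn_g", 0))
  enc$params$stem$bn$gamma <- u$p; vel[["stem_bn_g"]] <- u$v
  u <- upd(enc$params$stem$bn$beta, grads$trunk$stem_bn$dbeta,
           gv("stem_bn_b", 0))
  enc$params$stem$bn$beta <- u$p; vel[["stem_bn_b"]] <- u$v
  # stages
  for (s in seq_along(enc$params$stages)) {
    for (b in seq_along(enc$params$stages[[s]])) {
      blk <- enc$params$stages[[s]][[b]]
      g <- grads$trunk$stages[[s]][[b]]
      key <- sprintf("s%db%d", s, b)
      pieces <- list(
        list(get = function() blk$conv1, set = function(x) blk$conv1 <<- x,
             g = g$conv1, k = "c1"),
        list(get = function() blk$conv2, set = function(x) blk$conv2 <<- x,
             g = g$conv2, k = "c2"),
        list(get = function() blk$bn1$gamma,
             set = function(x) blk$bn1$gamma <<- x, g = g$bn1$dgamma,
             k = "b1g"),
        list(get = function() blk$bn1$beta,
             set = function(x) blk$bn1$beta <<- x, g = g$bn1$dbeta,
             k = "b1b"),
        list(get = function() blk$bn2$gamma,
             set = function(x) blk$bn2$gamma <<- x, g = g$bn2$dgamma,
             k = "b2g"),
        list(get = function() blk$bn2$beta,
             set = function(x) blk$bn2$beta <<- x, g = g$bn2$dbeta,
             k = "b2b"))
      if (!is.null(blk$short_w)) {
        pieces <- c(pieces, list(
          list(get = function() blk$short_w,
               set = function(x) blk$short_w <<- x, g = g$short_w, k = "sw"),
          list(get = function() blk$short_bn$gamma,
               set = function(x) blk$short_bn$gamma <<- x,
               g = g$short_bn$dgamma, k = "sbg"),
          list(get = function() blk$short_bn$beta,
               set = function(x) blk$short_bn$beta <<- x,
               g = g$short_bn$dbeta, k = "sbb")))
      }
      for (pc in pieces) {
        vk <- paste0(key, pc$k)
        u <- upd(pc$get(), pc$g, gv(vk, 0))
        pc$set(u$p); vel[[vk]] <- u$v
      }
      enc$params$stages[[s]][[b]] <- blk
    }
  }
  # dense heads
  for (head in c("bottleneck", "projection")) {
    for (i in seq_along(enc$params[[head]])) {
      vk <- paste0(head, i)
      u <- upd(enc$params[[head]][[i]]$W, grads[[head]][[i]]$W,
               gv(paste0(vk, "W"), 0))
      enc$params[[head]][[i]]$W <- u$p; vel[[paste0(vk, "W")]] <- u$v
      u <- upd(enc$params[[head]][[i]]$b, grads[[head]][[i]]$b,
               gv(paste0(vk, "b"), 0))
      enc$params[[head]][[i]]$b <- u$p; vel[[paste0(vk, "b")]] <- u$v
    }
  }
  list(enc = enc, vel = vel)
}

# Build the (vs,vs,vs,1,2N) input batch for a tibble of positive pairs.
pair_batch_views <- function(pairs, volume, skeletons, view_size,
                             augment = TRUE) {
  views <- vector("list", 2 * nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    skel <- skeletons[[as.character(pairs$segment_id[p])]]
    for (side in 1:2) {
      nid <- if (side == 1) pairs$node_a[p] else pairs$node_b[p]
      i <- node_index(skel, nid)
      v <- extract_view(volume,
                        c(skel$nodes$x[i], skel$nodes$y[i], skel$nodes$z[i]),
                        skel$segment_id, view_size)
      if (augment) v <- augment_view(v, "contrastive")
      views[[2 * (p - 1) + side]] <- v
    }
  }
  views_to_batch(views)
}

# Keep only pool rows whose both endpoints sit on voxels owned by their
# segment (a node can lose its voxel to an earlier cell at a collision).
filter_valid_pairs <- function(pools, volume, skeletons) {
  ok <- purrr::map(skeletons, valid_skeleton_nodes, volume = volume)
  keep <- purrr::map_lgl(seq_len(nrow(pools)), function(r) {
    v <- ok[[as.character(pools$segment_id[r])]]
    v[as.character(pools$node_a[r])] && v[as.character(pools$node_b[r])]
  })
  pools[keep, ]
}

#' Logical vector of skeleton nodes whose center voxel is owned by the
#' segment
#'
#' @param volume A [segmented_volume()].
#' @param skel A [skeleton()].
#' @return Named logical vector over node ids.
#' @export
valid_skeleton_nodes <- function(volume, skel) {
  shape <- dim(volume$segmentation)
  v <- floor(cbind(skel$nodes$x, skel$nodes$y, skel$nodes$z) /
               rep(volume$voxel_size_nm, each = nrow(skel$nodes))) + 1
  inb <- v[, 1] >= 1 & v[, 1] <= shape[1] & v[, 2] >= 1 &
    v[, 2] <= shape[2] & v[, 3] >= 1 & v[, 3] <= shape[3]
  out <- rep(FALSE, nrow(skel$nodes))
  idx <- v[inb, , drop = FALSE]
  out[inb] <- volume$segmentation[cbind(idx[, 1], idx[, 2], idx[, 3])] ==
    skel$segment_id
  names(out) <- skel$nodes$node_id
  out
}

#' Train the contrastive encoder
#'
#' Per step: draw a batch of positive pairs (segments unique within the
#' batch), extract and augment the two masked views of each pair, run the
#' encoder, and take a momentum-SGD step on the combined objective
#' NT-Xent(projections) + `w_dec` * decorrelation(embeddings).
#'
#' @param encoder A `segclr_encoder` from [build_encoder()] or a
#'   `segclr_checkpoint` to continue from.
#' @param volume A [segmented_volume()].
#' @param skeletons Named list of [skeleton()]s keyed by segment id.
#' @param pools Pair pools from [enumerate_pair_pools()] (invalid nodes are
#'   filtered automatically).
#' @param steps Number of optimizer steps (0 returns the initialization).
#' @param batch_pairs Positive pairs per batch (the reference run used
#'   512; desk-scale runs use 8).
#' @param tau NT-Xent temperature.
#' @param w_dec Weight of the decorrelation term.
#' @param base_lr Base learning rate at the 1,024-example reference batch;
#'   the actual rate is scaled by `2 * batch_pairs / 1024` with warmup and
#'   cosine decay.
#' @param momentum SGD momentum.
#' @param seed Integer seed; `NULL` continues the checkpoint's RNG stream.
#' @param schedule_steps Horizon of the warmup/cosine learning-rate
#'   schedule. Defaults to `steps` for fresh runs; when continuing a
#'   checkpoint the saved schedule position and horizon carry over, so an
#'   interrupted run resumes exactly where it left off.
#' @param reset_schedule Restart the schedule from its warmup (used by
#'   [refine_encoder()], which begins a fresh schedule on the new data).
#' @return A `segclr_checkpoint`: fields `encoder`, `trace` (tibble of
#'   per-step losses), `velocity`, `rng_state`, and the training settings.
#' @export
train_encoder <- function(encoder, volume, skeletons, pools, steps,
                          batch_pairs = 8, tau = 0.1, w_dec = 1.0,
                          base_lr = 0.2, momentum = 0.9, seed = NULL,
                          schedule_steps = NULL, reset_schedule = FALSE) {
  sched_pos <- 0
  sched_total <- NULL
  if (inherits(encoder, "segclr_checkpoint")) {
    ckpt <- encoder
    enc <- ckpt$encoder
    vel <- ckpt$velocity
    trace <- ckpt$trace
    if (is.null(seed) && !is.null(ckpt$rng_state)) {
      assign(".Random.seed", ckpt$rng_state, globalenv())
    }
    if (!reset_schedule && !is.null(ckpt$schedule)) {
      sched_pos <- ckpt$schedule$pos
      sched_total <- ckpt$schedule$total
    }
  } else {
    enc <- encoder
    vel <- NULL
    trace <- tibble::tibble(step = integer(0), nt_xent = numeric(0),
                            decorrelation = numeric(0), total = numeric(0))
  }
  sched_total <- schedule_steps %||% sched_total %||% steps
  sched_total <- max(sched_total, sched_pos + steps)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(enc, "segclr_encoder"))
  if (steps > 0) {
    pools <- filter_valid_pairs(pools, volume, skeletons)
    if (nrow(pools) == 0) stop("no valid positive pairs")
  }
  vs <- enc$config$view_size
  for (k in seq_len(steps)) {
    enc$step <- enc$step + 1L
    lr <- lr_at(sched_pos + k, sched_total, base_lr, 2 * batch_pairs)
    batch <- sample_pair_batch(pools, batch_pairs)
    x <- pair_batch_views(batch, volume, skeletons, vs)
    fw <- encoder_fw(enc, x, training = TRUE, project = TRUE)
    enc <- fw$enc
    nt <- nt_xent_with_grad(fw$projection, tau)
    dc <- decorrelation_with_grad(fw$embedding)
    total <- nt$loss + w_dec * dc$loss
    if (!is.finite(total)) {
      stop(sprintf(
        "training diverged at step %d (NT-Xent %.4g, decorrelation %.4g)",
        enc$step, nt$loss, dc$loss))
    }
    grads <- encoder_bw(enc, fw, d_embedding = w_dec * dc$grad,
                        d_projection = nt$grad)
    u <- sgd_update_encoder(enc, grads, vel, lr, momentum)
    enc <- u$enc
    vel <- u$vel
    trace <- dplyr::bind_rows(trace,
      tibble::tibble(step = enc$step, nt_xent = nt$loss,
                     decorrelation = dc$loss, total = total))
  }
  structure(list(encoder = enc, trace = trace, velocity = vel,
                 rng_state = get0(".Random.seed", globalenv()),
                 schedule = list(pos = sched_pos + steps,
                                 total = sched_total),
                 settings = list(batch_pairs = batch_pairs, tau = tau,
                                 w_dec = w_dec, base_lr = base_lr,
                                 momentum = momentum)),
            class = "segclr_checkpoint")
}

#' Continue training a checkpoint on a new dataset (refinement)
#'
#' All layers remain trainable; the learning rate keeps the base rate of
#' the original run, rescaled to the (typically much smaller) refinement
#' batch size, and the warmup/cosine schedule restarts over the
#' refinement run rather than continuing the original decayed schedule.
#'
#' @param checkpoint A `segclr_checkpoint`.
#' @param volume,skeletons,pools The new dataset.
#' @param steps Refinement steps.
#' @param batch_pairs Positive pairs per refinement batch (default 8).
#' @param seed Integer seed.
#' @return A `segclr_checkpoint`.
#' @export
refine_encoder <- function(checkpoint, volume, skeletons, pools, steps,
                           batch_pairs = 8, seed = NULL) {
  stopifnot(inherits(checkpoint, "segclr_checkpoint"))
  train_encoder(checkpoint, volume, skeletons, pools, steps = steps,
                batch_pairs = batch_pairs,
                tau = checkpoint$settings$tau,
                w_dec = checkpoint$settings$w_dec,
                base_lr = checkpoint$settings$base_lr,
                momentum = checkpoint$settings$momentum, seed = seed,
                reset_schedule = TRUE)
}

#' @export
print.segclr_checkpoint <- function(x, ...) {
  cat(sprintf("<segclr_checkpoint> step %d", x$encoder$step))
  if (nrow(x$trace) > 0) {
    cat(sprintf(", last loss %.4f", x$trace$total[nrow(x$trace)]))
  }
  cat("\n")
  invisible(x)
}

#' Compute embeddings for a batch of views
#'
#' Runs the encoder trunk and bottleneck only (the projection head is a
#' training-time construct and is dropped); batch norm uses the running
#' statistics, so the result is deterministic given the checkpoint.
#'
#' @param checkpoint A `segclr_checkpoint` (or a bare `segclr_encoder`).
#' @param views A list of `segclr_view`s or a prepared 5-D batch array.
#' @return Numeric matrix, one 64-d row per view.
#' @export
embed_views <- function(checkpoint, views) {
  enc <- if (inherits(checkpoint, "segclr_checkpoint")) {
    checkpoint$encoder
  } else {
    checkpoint
  }
  x <- if (is.list(views) && !is.array(views)) views_to_batch(views) else views
  stopifnot(dim(x)[1] == enc$config$view_size)
  encoder_fw(enc, x, training = FALSE, project = FALSE)$embedding
}

#' Save / load a checkpoint directory
#'
#' The architecture is stored as JSON next to the binary weights so a
#' checkpoint remains inspectable without loading it.
#' @param checkpoint A `segclr_checkpoint`.
#' @param dir Directory to create/use.
#' @return `dir` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- checkpoint$encoder$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(checkpoint, file.path(dir, "weights.rds"))
  if (nrow(checkpoint$trace) > 0) {
    readr::write_csv(checkpoint$trace, file.path(dir, "loss_trace.csv"))
  }
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
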