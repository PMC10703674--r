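# Fully supervised voxel classifier: the identical convolutional trunk as
# the contrastive encoder with the bottleneck and projection replaced by a
# classification softmax. Serves as the from-scratch baseline in
# label-efficiency comparisons.

#' Build a fully supervised voxel classifier
#'
#' @param config An [encoder_config()]; only the trunk part is used.
#' @param classes Character vector of class names.
#' @param seed Integer seed.
#' @return A `segclr_supervised` model.
#' @export
build_supervised <- function(config, classes, seed = 1L) {
  enc <- build_encoder(config, seed)
  trunk_out <- config$stage_widths[length(config$stage_widths)]
  set.seed(derive_seed(seed, 7))
  enc$params$bottleneck <- NULL
  enc$params$projection <- NULL
  head <- dense_init(trunk_out, length(classes))
  structure(list(encoder = enc, head = head, classes = classes),
            class = "segclr_supervised")
}

#' Train the supervised baseline on labeled views
#'
#' Classes are rebalanced by cyclic upsampling; augmentation is the
#' supervised mode (reflections plus 90-degree rotations, no photometric
#' jitter). Momentum SGD on the cross-entropy.
#'
#' @param model A `segclr_supervised` from [build_supervised()].
#' @param views List of `segclr_view`s.
#' @param labels Label per view.
#' @param steps Optimizer steps.
#' @param batch_size Views per step.
#' @param lr Learning rate (default 0.003).
#' @param momentum SGD momentum.
#' @param seed Integer seed.
#' @return The trained `segclr_supervised` model (with `trace`).
#' @export
train_supervised <- function(model, views, labels, steps, batch_size = 8,
                             lr = 0.003, momentum = 0.9, seed = 1L) {
  stopifnot(length(views) == length(labels))
  set.seed(seed)
  y <- factor(labels, levels = model$classes)
  if (anyNA(y)) stop("labels outside the model's class set")
  pool <- rebalance_upsample(y)
  K <- length(model$classes)
  Yoh <- diag(K)
  enc <- model$encoder
  head <- model$head
  vel <- NULL
  vel_head <- list(W = 0, b = 0)
  trace <- numeric(steps)
  for (k in seq_len(steps)) {
    idx <- sample(pool, min(batch_size, length(pool)))
    batch_views <- purrr::map(views[idx], augment_view, mode = "supervised")
    x <- views_to_batch(batch_views)
    tf <- trunk_fw_conv(enc, x, training = TRUE)
    enc <- tf$enc
    hf <- dense_fw(tf$features, head)
    ce <- cross_entropy_grad(hf$y, Yoh[as.integer(y[idx]), , drop = FALSE])
    trace[k] <- ce$loss
    hb <- dense_bw(ce$dlogits, head, hf$cache)
    grads <- list(trunk = trunk_bw_conv(enc, tf$cache, hb$dx),
                  bottleneck = list(), projection = list())
    # head update
    vel_head$W <- momentum * vel_head$W + hb$dW
    vel_head$b <- momentum * vel_head$b + hb$db
    head$W <- head$W - lr * vel_head$W
    head$b <- head$b - lr * vel_head$b
    u <- sgd_update_encoder(enc, grads, vel, lr, momentum)
    enc <- u$enc
    vel <- u$vel
  }
  model$encoder <- enc
  model$head <- head
  model$trace <- trace
  model
}

#' @export
predict.segclr_supervised <- function(object, views,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.list(views) && !is.array(views)) views_to_batch(views) else views
  tf <- trunk_fw_conv(object$encoder, x, training = FALSE)
  p <- softmax_rows(dense_fw(tf$features, object$head)$y)
  colnames(p) <- object$classes
  if (type == "class") {
    return(object$classes[max.col(p, ties.method = "first")])
  }
  tibble::as_tibble(p)
}
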