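#' Dempster-Shafer predictive uncertainty
#'
#' `u(x) = K / (K + sum_k exp(h_k(x)))` for K class logits `h_k`. Large
#' logits (confident evidence for some class) drive u toward 0; at all-zero
#' logits u is exactly 0.5. Increasing any logit strictly decreases u.
#'
#' @param logits Numeric vector (one example) or matrix (rows = examples).
#' @param K Number of classes; defaults to the logit dimension.
#' @return Uncertainty in (0, 1), one value per example.
#' @export
dempster_shafer <- function(logits, K = NULL) {
  h <- if (is.null(dim(logits))) matrix(logits, nrow = 1) else as.matrix(logits)
  if (!all(is.finite(h))) stop("non-finite logits")
  K <- K %||% ncol(h)
  if (K < 2) stop("need at least 2 classes")
  u <- K / (K + rowSums(exp(h)))
  if (is.null(dim(logits))) u[1] else u
}

#' Mean-field adjustment of logits by predictive variance
#'
#' `h_lambda(x) = h(x) / sqrt(1 + lambda * sigma^2(x))`, the closed-form
#' replacement for Monte-Carlo averaging of a Gaussian-process posterior
#' over logits; `sigma2` is the per-example predictive variance shared
#' across that example's logits.
#'
#' @param h Logit vector or matrix (rows = examples).
#' @param sigma2 Predictive variance per example (>= 0).
#' @param lambda Mean-field coefficient (>= 0; the classic choice is
#'   `3 / pi^2`).
#' @return Adjusted logits, same shape as `h`.
#' @export
mean_field_adjust <- function(h, sigma2, lambda = 3 / pi^2) {
  stopifnot(all(sigma2 >= 0), lambda >= 0)
  if (is.null(dim(h))) return(h / sqrt(1 + lambda * sigma2))
  sweep(as.matrix(h), 1, sqrt(1 + lambda * sigma2), "/")
}

#' Fit a spectral-normalized Gaussian-process classifier (SNGP)
#'
#' The two-module residual trunk of [train_resnet2()] with its hidden
#' weight matrices spectrally normalized during training (power-iteration
#' estimate, rescaled when the top singular value exceeds `sn_bound`), and
#' the output layer replaced by a random-Fourier-feature Gaussian process:
#' `phi(x) = sqrt(2/m) cos(W h(x) + b)` with fixed random `W`, `b`, and
#' trainable class weights `beta`. After training, a Laplace approximation
#' of the posterior precision over the random features yields a
#' per-example predictive variance `sigma^2(x) = phi' P^{-1} phi`.
#'
#' @inheritParams train_resnet2
#' @param n_rff Number of random Fourier features (default 1024).
#' @param sn_bound Spectral norm bound on hidden layers (default 0.95).
#' @param length_scale Gaussian-process kernel length scale.
#' @param ridge Prior precision (ridge) of the Laplace covariance.
#' @return A `segclr_sngp` model.
#' @export
fit_sngp <- function(embeddings, labels, seed = 1L, width = 128,
                     n_rff = 1024, sn_bound = 0.95, length_scale = 2,
                     epochs = 60, batch_size = 64, lr = 0.01, ridge = 1) {
  X <- as.matrix(embeddings)
  y <- factor(labels)
  check_class_counts(y)
  set.seed(seed)
  K <- nlevels(y)
  params <- trunk_init(ncol(X), width)
  W_rff <- matrix(rnorm(width * n_rff), width, n_rff) / length_scale
  b_rff <- runif(n_rff, 0, 2 * pi)
  params$beta <- matrix(rnorm(n_rff * K, 0, 0.01), n_rff, K)
  sn_names <- grep("^W", names(params), value = TRUE)
  sn_names <- setdiff(sn_names, "beta")
  sn_state <- purrr::map(setNames(sn_names, sn_names), function(nm)
    rnorm(nrow(params[[nm]])) |> (\(u) u / sqrt(sum(u^2)))())
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  st <- adam_state(params)
  n <- nrow(X)
  rff_fw <- function(h) {
    pre <- sweep(h %*% W_rff, 2, b_rff, "+")
    sqrt(2 / n_rff) * cos(pre)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      fw <- trunk_forward(params, X[idx, , drop = FALSE])
      pre <- sweep(fw$h %*% W_rff, 2, b_rff, "+")
      phi <- sqrt(2 / n_rff) * cos(pre)
      logits <- phi %*% params$beta
      ce <- cross_entropy_grad(logits, Y[idx, , drop = FALSE])
      dphi <- ce$dlogits %*% t(params$beta)
      dpre <- -dphi * sqrt(2 / n_rff) * sin(pre)
      dh <- dpre %*% t(W_rff)
      grads <- trunk_backward(params, fw$caches, dh)
      grads$beta <- t(phi) %*% ce$dlogits
      u <- adam_update(params, grads, st, lr)
      params <- u$params
      st <- u$state
      sn <- apply_spectral_norm(params, sn_state, sn_bound)
      params <- sn$params
      sn_state <- sn$sn_state
    }
  }
  # Posterior precision over random features (Gaussian-likelihood Laplace
  # covariance, shared across classes): P = ridge*I + Phi' Phi, so
  # directions spanned by the training features carry low variance and
  # unfamiliar inputs keep variance near the prior.
  fw <- trunk_forward(params, X)
  phi <- rff_fw(fw$h)
  P <- ridge * diag(n_rff) + crossprod(phi)
  P_chol <- chol(P)
  structure(list(params = params, W_rff = W_rff, b_rff = b_rff,
                 P_chol = P_chol, classes = levels(y), n_rff = n_rff,
                 width = width),
            class = "segclr_sngp")
}

#' Predict with an SNGP model
#'
#' Returns raw logits, the Gaussian-process predictive variance, the
#' mean-field adjusted logits, softmax probabilities from the adjusted
#' logits and the Dempster-Shafer uncertainty computed on the adjusted
#' logits.
#'
#' @param object A `segclr_sngp`.
#' @param newdata Embedding matrix/tibble.
#' @param lambda Mean-field coefficient (default `3 / pi^2`).
#' @param ... Unused.
#' @return Tibble with `pred_class`, `u`, `sigma2`, plus probability
#'   columns per class; logit matrices in attributes `logits` and
#'   `adjusted_logits`.
#' @export
predict.segclr_sngp <- function(object, newdata, lambda = 3 / pi^2, ...) {
  X <- as.matrix(newdata)
  fw <- trunk_forward(object$params, X)
  pre <- sweep(fw$h %*% object$W_rff, 2, object$b_rff, "+")
  phi <- sqrt(2 / object$n_rff) * cos(pre)
  logits <- phi %*% object$params$beta
  v <- backsolve(object$P_chol, forwardsolve(t(object$P_chol), t(phi)))
  sigma2 <- colSums(t(phi) * v)
  h_adj <- mean_field_adjust(logits, sigma2, lambda)
  p <- softmax_rows(h_adj)
  colnames(p) <- object$classes
  u <- dempster_shafer(h_adj)
  out <- dplyr::bind_cols(
    tibble::tibble(
      pred_class = object$classes[max.col(p, ties.method = "first")],
      u = u, sigma2 = sigma2),
    tibble::as_tibble(p))
  attr(out, "logits") <- logits
  attr(out, "adjusted_logits") <- h_adj
  out
}

#' Calibrate the in/out uncertainty threshold
#'
#' Scans all midpoints between sorted unique uncertainty values and
#' returns the threshold maximizing the F1 of out-of-distribution
#' detection (OOD = positive, predicted when `u > threshold`); ties go to
#' the smallest threshold.
#'
#' @param u Uncertainty values.
#' @param is_ood Logical: TRUE for out-of-distribution examples.
#' @return List: `threshold`, `f1`.
#' @export
calibrate_threshold <- function(u, is_ood) {
  stopifnot(length(u) == length(is_ood))
  is_ood <- as.logical(is_ood)
  if (!any(is_ood) || all(is_ood)) stop("need both in- and out examples")
  su <- sort(unique(u))
  if (length(su) < 2) stop("degenerate single-valued uncertainty")
  cands <- (head(su, -1) + tail(su, -1)) / 2
  f1_at <- function(thr) {
    pred <- u > thr
    tp <- sum(pred & is_ood)
    if (tp == 0) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(is_ood)
    2 * prec * rec / (prec + rec)
  }
  f1s <- vapply(cands, f1_at, numeric(1))
  best <- which.max(f1s)  # first (= smallest threshold) on ties
  list(threshold = cands[best], f1 = f1s[best])
}

#' Out-of-distribution evaluation protocol
#'
#' Cell-level k-fold cross-validation on the in-distribution classes
#' only: per fold, a classifier is trained on the training folds,
#' predictions are made for the held-out in-distribution cells plus the
#' full OOD pool, the uncertainty threshold is calibrated on a set-aside
#' half of that test set, predictions with `u` above the threshold are
#' relabeled "OOD", and class-wise F1 (OOD as its own class) is computed
#' on the other half with example weights scaled so OOD totals 50% and
#' each in-distribution class shares the other 50% equally.
#'
#' @param embeddings In-distribution embedding rows.
#' @param cell_ids,labels Cell id and class per row.
#' @param ood_embeddings OOD embedding rows (their true class is "OOD").
#' @param fit_fun Model fitting function, e.g. [fit_sngp()] (or
#'   [train_resnet2()] for a variance-free baseline).
#' @param predict_fun Function(model, X) returning a tibble with
#'   `pred_class` and `u` columns; defaults to [predict.segclr_sngp()].
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return List: `folds` (per-fold tibble: threshold, f1 by class, mean),
#'   `mean_f1`.
#' @export
ood_protocol <- function(embeddings, cell_ids, labels, ood_embeddings,
                         fit_fun = fit_sngp,
                         predict_fun = function(m, X) predict(m, X),
                         n_folds = 5, seed = 1L) {
  X <- as.matrix(embeddings)
  Xo <- as.matrix(ood_embeddings)
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 in-distribution classes")
  cells <- unique(cell_ids)
  set.seed(derive_seed(seed, 1))
  fold_of <- sample(rep_len(seq_len(n_folds), length(cells)))
  names(fold_of) <- cells
  fold_rows <- list()
  for (f in seq_len(n_folds)) {
    te_cells <- cells[fold_of == f]
    tr <- !(cell_ids %in% te_cells)
    if (length(unique(y[tr])) < length(classes)) {
      stop("fold ", f, " lost an in-distribution class")
    }
    fit <- fit_fun(X[tr, , drop = FALSE], y[tr],
                   seed = derive_seed(seed, 10 + f))
    te_idx <- which(!tr)
    pr_in <- predict_fun(fit, X[te_idx, , drop = FALSE])
    pr_ood <- predict_fun(fit, Xo)
    truth <- c(y[te_idx], rep("OOD", nrow(Xo)))
    pred0 <- c(pr_in$pred_class, pr_ood$pred_class)
    uu <- c(pr_in$u, pr_ood$u)
    # set aside half for threshold calibration
    set.seed(derive_seed(seed, 20 + f))
    half <- sample(c(TRUE, FALSE), length(uu), replace = TRUE)
    cal <- calibrate_threshold(uu[half], truth[half] == "OOD")
    eval_idx <- which(!half)
    pred <- pred0[eval_idx]
    pred[uu[eval_idx] > cal$threshold] <- "OOD"
    tr_eval <- truth[eval_idx]
    # class weights: OOD 50%, each in-dist class an equal share of 50%
    wts <- ifelse(tr_eval == "OOD", 0.5 / max(sum(tr_eval == "OOD"), 1),
                  0.5 / length(classes) /
                    pmax(table(tr_eval)[tr_eval], 1))
    f1c <- weighted_f1_by_class(tr_eval, pred, c(classes, "OOD"), wts)
    fold_rows[[f]] <- tibble::tibble(fold = f, class = names(f1c),
                                     f1 = unname(f1c),
                                     threshold = cal$threshold)
  }
  folds <- dplyr::bind_rows(fold_rows)
  per_fold <- folds |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(f1 = mean(.data$f1), .groups = "drop")
  list(folds = folds, mean_f1 = mean(per_fold$f1))
}

# Class-wise F1 with per-example weights (used to rescale OOD prevalence).
weighted_f1_by_class <- function(truth, pred, classes, w) {
  vapply(setNames(classes, classes), function(cl) {
    tp <- sum(w[truth == cl & pred == cl])
    fp <- sum(w[truth != cl & pred == cl])
    fn <- sum(w[truth == cl & pred != cl])
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
}
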