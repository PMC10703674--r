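#' Train a linear probe on embeddings
#'
#' Multinomial logistic regression with softmax output, the standard
#' readout for testing what information an embedding space carries.
#'
#' @param embeddings Numeric matrix or tibble of embedding rows.
#' @param labels Character/factor labels, one per row (>= 2 classes,
#'   >= 3 examples per class).
#' @param seed Integer seed (the fit itself is deterministic; the seed
#'   pins any RNG used by downstream resampling helpers).
#' @param maxit Optimizer iteration budget.
#' @return A `segclr_classifier` ("linear").
#' @export
train_linear <- function(embeddings, labels, seed = 1L, maxit = 200) {
  X <- as.matrix(embeddings)
  y <- factor(labels)
  check_class_counts(y)
  set.seed(seed)
  df <- data.frame(.y = y, X)
  utils::capture.output(
    fit <- nnet::multinom(.y ~ ., data = df, maxit = maxit, trace = FALSE,
                          MaxNWts = 100000))
  structure(list(kind = "linear", fit = fit, classes = levels(y),
                 feature_names = colnames(df)[-1]),
            class = "segclr_classifier")
}

check_class_counts <- function(y) {
  tab <- table(y)
  if (length(tab) < 2) stop("need at least 2 classes")
  if (any(tab < 3)) stop("need at least 3 examples per class")
  invisible(tab)
}

#' Train a shallow two-module residual classifier
#'
#' A two-block residual fully-connected network ("ResNet-2") with softmax
#' output, the aggregation-level cell type classifier. Trained with Adam
#' on the cross-entropy.
#'
#' @inheritParams train_linear
#' @param width Hidden width (default 128).
#' @param epochs,batch_size,lr Training schedule.
#' @return A `segclr_classifier` ("resnet2").
#' @export
train_resnet2 <- function(embeddings, labels, seed = 1L, width = 128,
                          epochs = 60, batch_size = 64, lr = 0.01) {
  X <- as.matrix(embeddings)
  y <- factor(labels)
  check_class_counts(y)
  set.seed(seed)
  K <- nlevels(y)
  params <- trunk_init(ncol(X), width)
  params$W_out <- he_mat(width, K) * 0.1
  params$b_out <- numeric(K)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  st <- adam_state(params)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      fw <- trunk_forward(params, X[idx, , drop = FALSE])
      logits <- sweep(fw$h %*% params$W_out, 2, params$b_out, "+")
      ce <- cross_entropy_grad(logits, Y[idx, , drop = FALSE])
      grads <- trunk_backward(params, fw$caches,
                              ce$dlogits %*% t(params$W_out))
      grads$W_out <- t(fw$h) %*% ce$dlogits
      grads$b_out <- colSums(ce$dlogits)
      u <- adam_update(params, grads, st, lr)
      params <- u$params
      st <- u$state
    }
  }
  structure(list(kind = "resnet2", params = params, classes = levels(y),
                 width = width),
            class = "segclr_classifier")
}

#' Predict class probabilities
#'
#' @param object A `segclr_classifier`.
#' @param newdata Embedding matrix/tibble.
#' @param type "prob" for a probability tibble, "class" for labels.
#' @param ... Unused.
#' @return Tibble of per-class probabilities or a character vector.
#' @export
predict.segclr_classifier <- function(object, newdata,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (object$kind == "linear") {
    df <- data.frame(X)
    names(df) <- object$feature_names
    p <- predict(object$fit, newdata = df, type = "probs")
    if (is.null(dim(p))) {  # two-class fit returns P(second level)
      p <- cbind(1 - p, p)
    }
    colnames(p) <- object$classes
  } else {
    fw <- trunk_forward(object$params, X)
    logits <- sweep(fw$h %*% object$params$W_out, 2, object$params$b_out,
                    "+")
    p <- softmax_rows(logits)
    colnames(p) <- object$classes
  }
  if (type == "class") {
    return(object$classes[max.col(p, ties.method = "first")])
  }
  tibble::as_tibble(p)
}

#' @export
print.segclr_classifier <- function(x, ...) {
  cat(sprintf("<segclr_classifier> %s over %d classes (%s)\n", x$kind,
              length(x$classes), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Subsample a training set under class-floor constraints
#'
#' Uniform subsample of `target_n` indices, redrawn until every class
#' keeps at least `min_per_class` examples and at least `min_frac` of the
#' drawn sample, the guard used when probing label efficiency at small
#' sample sizes.
#'
#' @param labels Full label vector.
#' @param target_n Sample size.
#' @param seed Integer seed.
#' @param min_per_class Minimum examples per class (default 3).
#' @param min_frac Minimum fraction of the drawn sample per class
#'   (default 0.10).
#' @param max_tries Redraw budget before declaring infeasibility.
#' @return Integer index vector of length `target_n`.
#' @export
subsample_training_set <- function(labels, target_n, seed = 1L,
                                   min_per_class = 3, min_frac = 0.10,
                                   max_tries = 1000) {
  y <- factor(labels)
  K <- nlevels(y)
  floor_n <- max(min_per_class, ceiling(min_frac * target_n))
  if (target_n > length(y)) stop("target_n exceeds dataset size")
  if (K * floor_n > target_n) {
    stop(sprintf("infeasible: %d classes x floor %d > target %d", K,
                 floor_n, target_n))
  }
  if (any(table(y) < floor_n)) stop("a class has too few examples overall")
  set.seed(seed)
  if (target_n == length(y)) return(seq_along(y))
  for (i in seq_len(max_tries)) {
    idx <- sample.int(length(y), target_n)
    if (all(table(y[idx]) >= floor_n)) return(sort(idx))
  }
  stop("could not satisfy class floors within the redraw budget")
}

#' Rebalance classes by cyclic upsampling
#'
#' Repeats each class's indices cyclically until every class matches the
#' most numerous class.
#'
#' @param labels Label vector.
#' @return Integer index vector (length = max class count x n classes).
#' @export
rebalance_upsample <- function(labels) {
  y <- factor(labels)
  tab <- table(y)
  m <- max(tab)
  unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    rep_len(idx, m)
  }), use.names = FALSE)
}

#' Collapse classifier probabilities onto merged classes
#'
#' Sums the probabilities of the member classes of each merged class
#' (e.g. all pyramidal subtypes onto a single pyramidal class).
#'
#' @param probabilities Matrix/tibble of per-class probabilities with
#'   column names.
#' @param mapping Named character vector: `original class -> merged class`.
#'   Every probability column must be mapped.
#' @return Tibble of merged-class probabilities (rows still sum to 1).
#' @export
collapse_classes <- function(probabilities, mapping) {
  p <- as.matrix(probabilities)
  miss <- setdiff(colnames(p), names(mapping))
  if (length(miss) > 0) {
    stop("mapping misses classes: ", paste(miss, collapse = ", "))
  }
  merged <- unique(unname(mapping[colnames(p)]))
  out <- sapply(merged, function(m)
    rowSums(p[, colnames(p)[mapping[colnames(p)] == m], drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, merged))
  tibble::as_tibble(out)
}

#' Cell-level cross-validated classification
#'
#' The cell-typing evaluation protocol: cells (not embedding rows) are
#' split 75/25 per class into train/test, `n_repeats` times; per run,
#' `samples_per_run` training embeddings are drawn equally across classes
#' (repeating minority examples), the classifier is fit and applied to the
#' class-rebalanced test side; F1 is computed per class and averaged.
#' Confusion counts are pooled over runs and then resampled to equal class
#' totals.
#'
#' @param embeddings Embedding matrix/tibble (one row per embedding node).
#' @param cell_ids Cell (segment) id per row; splits never separate rows
#'   of one cell.
#' @param labels Class label per row (constant within a cell).
#' @param classifier_fun Fitting function, e.g. [train_resnet2()] or
#'   [train_linear()]; called as `classifier_fun(X, y, seed)`.
#' @param n_repeats Number of random splits (default 10).
#' @param train_frac Fraction of cells per class for training (default
#'   0.75; every class needs >= 4 cells).
#' @param samples_per_run Training embeddings drawn per run.
#' @param seed Integer seed.
#' @return List: `runs` (tibble of per-run macro F1), `per_class`
#'   (mean per-class F1), `mean_f1`, `confusion` (pooled, class-balanced).
#' @export
cell_level_cv <- function(embeddings, cell_ids, labels, classifier_fun,
                          n_repeats = 10, train_frac = 0.75,
                          samples_per_run = 1000, seed = 1L) {
  X <- as.matrix(embeddings)
  y <- as.character(labels)
  cells <- tibble::tibble(cell = cell_ids, label = y) |>
    dplyr::distinct()
  if (anyDuplicated(cells$cell)) stop("a cell carries two labels")
  cc <- table(cells$label)
  if (any(cc < 4)) {
    stop("every class needs at least 4 cells for a 75/25 cell split")
  }
  classes <- sort(unique(y))
  runs <- list()
  pooled_truth <- character(0)
  pooled_pred <- character(0)
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, r))
    train_cells <- unlist(lapply(classes, function(cl) {
      cs <- cells$cell[cells$label == cl]
      sample(cs, round(train_frac * length(cs)))
    }))
    is_train <- cell_ids %in% train_cells
    # equal-class training draw (repeat minority examples as needed)
    per_class_n <- ceiling(samples_per_run / length(classes))
    tr_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(is_train & y == cl)
      if (length(idx) == 0) stop("class missing from training cells: ", cl)
      sample(idx, per_class_n, replace = length(idx) < per_class_n)
    }))
    fit <- classifier_fun(X[tr_idx, , drop = FALSE], y[tr_idx],
                          seed = derive_seed(seed, 1000 + r))
    te_idx <- which(!is_train)
    if (length(te_idx) == 0) stop("empty test side")
    bal <- te_idx[rebalance_upsample(y[te_idx])]
    pred <- predict(fit, X[bal, , drop = FALSE], type = "class")
    sc <- f1_scores(y[bal], pred, classes)
    runs[[r]] <- sc$per_class |>
      dplyr::mutate(run = r)
    pooled_truth <- c(pooled_truth, y[bal])
    pooled_pred <- c(pooled_pred, pred)
  }
  run_tbl <- dplyr::bind_rows(runs)
  per_class <- run_tbl |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(f1 = mean(.data$f1), .groups = "drop")
  # pooled confusion at equal class totals
  set.seed(derive_seed(seed, 99))
  bal2 <- rebalance_upsample(pooled_truth)
  confusion <- confusion_tibble(pooled_truth[bal2], pooled_pred[bal2],
                                classes)
  structure(list(runs = run_tbl, per_class = per_class,
                 mean_f1 = mean(per_class$f1), confusion = confusion,
                 classes = classes, n_repeats = n_repeats),
            class = "segclr_cv")
}

#' @export
print.segclr_cv <- function(x, ...) {
  cat(sprintf("<segclr_cv> %d runs, mean F1 = %.3f\n", x$n_repeats,
              x$mean_f1))
  invisible(x)
}
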