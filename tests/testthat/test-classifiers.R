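blob_data <- function(n_per, centers, sd = 0.05, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, y = rep(rownames(centers), each = n_per))
}

test_that("linear probe nails separable and near-separable problems", {
  d <- blob_data(20, rbind(a = c(0, 0), b = c(3, 3)))
  fit <- train_linear(d$X, d$y, seed = 1)
  expect_equal(mean(predict(fit, d$X, type = "class") == d$y), 1)
  p <- predict(fit, d$X, type = "prob")
  expect_equal(rowSums(as.matrix(p)), rep(1, nrow(p)), tolerance = 1e-6)
  # duplicating every example leaves the decision function unchanged
  # (checked on overlapping blobs, where the likelihood optimum is unique)
  dd <- blob_data(40, rbind(a = c(0, 0), b = c(1.2, 1.2)), sd = 0.8,
                  seed = 9)
  fitd <- train_linear(dd$X, dd$y, seed = 1, maxit = 500)
  fitd2 <- train_linear(rbind(dd$X, dd$X), c(dd$y, dd$y), seed = 1,
                        maxit = 500)
  grid <- as.matrix(expand.grid(seq(-1, 2, 0.25), seq(-1, 2, 0.25)))
  colnames(grid) <- colnames(dd$X)
  expect_equal(as.matrix(predict(fitd, grid, type = "prob")),
               as.matrix(predict(fitd2, grid, type = "prob")),
               tolerance = 1e-3)
  # three tight Gaussian blobs
  d3 <- blob_data(30, rbind(a = c(0, 0, 0), b = c(2, 0, 2),
                            c = c(0, 2, -2)), sd = 0.05, seed = 2)
  fit3 <- train_linear(d3$X, d3$y, seed = 1)
  expect_gte(macro_f1(d3$y, predict(fit3, d3$X, type = "class")), 0.99)
  expect_error(train_linear(d$X, rep("a", nrow(d$X))), "2 classes")
})

test_that("the residual classifier solves XOR where the probe cannot", {
  set.seed(3)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n, 0, 0.1), ncol = 2) +
               matrix(rep(c(0, 0), n), ncol = 2, byrow = TRUE),
             matrix(rnorm(2 * n, 0, 0.1), ncol = 2) +
               matrix(rep(c(1, 1), n), ncol = 2, byrow = TRUE),
             matrix(rnorm(2 * n, 0, 0.1), ncol = 2) +
               matrix(rep(c(0, 1), n), ncol = 2, byrow = TRUE),
             matrix(rnorm(2 * n, 0, 0.1), ncol = 2) +
               matrix(rep(c(1, 0), n), ncol = 2, byrow = TRUE))
  y <- rep(c("same", "same", "diff", "diff"), each = n)
  rn <- train_resnet2(X, y, seed = 4, epochs = 80)
  acc_rn <- mean(predict(rn, X, type = "class") == y)
  lin <- train_linear(X, y, seed = 4)
  acc_lin <- mean(predict(lin, X, type = "class") == y)
  expect_gte(acc_rn, 0.95)
  expect_lt(acc_lin, 0.7)
  # determinism given the seed
  rn2 <- train_resnet2(X, y, seed = 4, epochs = 80)
  expect_equal(predict(rn, X, type = "prob"),
               predict(rn2, X, type = "prob"), tolerance = 1e-12)
})

test_that("subsampling respects the class floors", {
  y <- rep(c("a", "b"), c(50, 30))
  # full-dataset request returns the identity subset
  expect_equal(subsample_training_set(y, 80), seq_len(80))
  # two classes, target 6: at least 3 each
  for (s in 1:20) {
    idx <- subsample_training_set(y, 6, seed = s)
    expect_true(all(table(y[idx]) >= 3))
    expect_length(idx, 6)
  }
  # larger draws keep every class at >= 10% of the sample
  y3 <- rep(c("a", "b", "c"), c(200, 40, 40))
  for (s in 1:50) {
    idx <- subsample_training_set(y3, 60, seed = s)
    expect_true(all(table(y3[idx]) >= max(3, ceiling(0.10 * 60))))
  }
  expect_error(subsample_training_set(y, 4), "infeasible")
})

test_that("upsampling rebalances to the majority count cyclically", {
  y <- c(rep("big", 5), rep("small", 3))
  idx <- rebalance_upsample(y)
  expect_equal(unname(table(y[idx])), c(5L, 5L), ignore_attr = TRUE)
  # the minority's first indices repeat in cyclic order
  expect_equal(idx[y[idx] == "small"], c(6L, 7L, 8L, 6L, 7L))
  # balanced input unchanged
  yb <- rep(c("x", "y"), each = 4)
  expect_equal(sort(rebalance_upsample(yb)), 1:8)
})

test_that("class collapsing sums member probabilities", {
  p <- matrix(c(0.2, 0.2, 0.1, 0.1, 0.4), 1,
              dimnames = list(NULL, paste0("c", 1:5)))
  mapping <- c(c1 = "m", c2 = "m", c3 = "m", c4 = "m", c5 = "other")
  out <- collapse_classes(p, mapping)
  expect_equal(as.numeric(out$m), 0.6)
  expect_equal(as.numeric(out$other), 0.4)
  # identity mapping is a no-op
  idm <- setNames(colnames(p), colnames(p))
  expect_equal(as.matrix(collapse_classes(p, idm)), p, ignore_attr = TRUE)
  # normalization preserved on random inputs
  set.seed(5)
  P <- matrix(runif(40), 8, 5, dimnames = list(NULL, paste0("c", 1:5)))
  P <- P / rowSums(P)
  expect_equal(rowSums(as.matrix(collapse_classes(P, mapping))),
               rep(1, 8))
  expect_error(collapse_classes(p, mapping[-2]), "misses")
})

test_that("F1 computation matches the hand oracle on random label sets", {
  set.seed(6)
  for (rep in 1:20) {
    classes <- letters[1:sample(2:5, 1)]
    n <- sample(30:120, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(classes, n, replace = TRUE))
    expect_equal(macro_f1(truth, pred, classes),
                 oracle_macro_f1(truth, pred, classes), tolerance = 1e-12)
  }
})

test_that("cell-level CV keeps cells apart and scores known classifiers
          exactly", {
  set.seed(7)
  n_cells <- 12
  rows_per <- 8
  cell <- rep(seq_len(3 * n_cells), each = rows_per)
  label <- rep(rep(c("a", "b", "c"), each = n_cells), each = rows_per)
  X <- matrix(rnorm(length(cell) * 3, 0, 0.05), ncol = 3) +
    (match(label, c("a", "b", "c"))) %o% c(1, -1, 0.5)
  # a perfect classifier: tight blobs are linearly separable
  cv <- cell_level_cv(X, cell, label, train_linear, n_repeats = 3,
                      samples_per_run = 60, seed = 1)
  expect_equal(cv$mean_f1, 1)
  conf <- cv$confusion
  expect_true(all(conf$n[conf$truth != conf$estimate] == 0))
  # majority-constant classifier: recall 1 for one class, 0 elsewhere;
  # on a balanced test set macro F1 = (2 / (k + 1)) / k
  constant_fit <- function(X, y, seed) {
    structure(list(cls = "a"), class = "constant_clf")
  }
  assign("predict.constant_clf",
         function(object, newdata, type = "class", ...)
           rep(object$cls, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.constant_clf", envir = globalenv()), add = TRUE)
  cv2 <- cell_level_cv(X, cell, label, constant_fit, n_repeats = 2,
                       samples_per_run = 30, seed = 2)
  k <- 3
  expect_equal(cv2$mean_f1, (2 / (k + 1)) / k, tolerance = 1e-12)
  # split contract: no cell on both sides of any run (verified via the
  # protocol's own split RNG)
  cells_tbl <- unique(data.frame(cell = cell, label = label))
  for (r in 1:3) {
    set.seed(segclr:::derive_seed(1, r))
    tr_cells <- unlist(lapply(sort(unique(label)), function(cl) {
      cs <- cells_tbl$cell[cells_tbl$label == cl]
      sample(cs, round(0.75 * length(cs)))
    }))
    expect_length(intersect(tr_cells, setdiff(cells_tbl$cell, tr_cells)), 0)
  }
  expect_error(
    cell_level_cv(X[1:24, ], cell[1:24], label[1:24], train_linear,
                  n_repeats = 1, samples_per_run = 10),
    "4 cells")
})
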