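test_that("Dempster-Shafer uncertainty matches the scalar formula", {
  # forced value at zero logits, any K
  for (K in 2:6) expect_equal(dempster_shafer(rep(0, K)), 0.5)
  expect_equal(dempster_shafer(c(log(2), log(2))), 1 / 3, tolerance = 1e-15)
  # scalar plug-in oracle on 1,000 random inputs
  set.seed(1)
  for (i in 1:1000) {
    K <- sample(2:8, 1)
    h <- rnorm(K, 0, 3)
    expect_equal(dempster_shafer(h), K / (K + sum(exp(h))),
                 tolerance = 1e-12)
  }
  # strict monotonicity: raising any logit lowers u
  h <- rnorm(4)
  for (k in 1:4) {
    h2 <- h
    h2[k] <- h2[k] + 0.3
    expect_lt(dempster_shafer(h2), dempster_shafer(h))
  }
  expect_error(dempster_shafer(c(1, NA)), "non-finite")
  # matrix form agrees with row-wise scalar evaluation
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(dempster_shafer(H),
               apply(H, 1, function(r) 3 / (3 + sum(exp(r)))))
})

test_that("mean-field adjustment matches the scalar formula", {
  expect_equal(mean_field_adjust(1, 3, 1), 0.5)
  # identities at lambda = 0 and sigma2 = 0
  h <- rnorm(5)
  expect_equal(mean_field_adjust(h, 2.5, 0), h)
  expect_equal(mean_field_adjust(h, 0, 7), h)
  set.seed(2)
  for (i in 1:1000) {
    hh <- rnorm(1, 0, 2)
    s2 <- runif(1, 0, 5)
    lam <- runif(1, 0, 3)
    expect_equal(mean_field_adjust(hh, s2, lam),
                 hh / sqrt(1 + lam * s2), tolerance = 1e-12)
  }
  # matrix rows share their example's variance
  H <- matrix(rnorm(6), 2, 3)
  s2 <- c(1, 4)
  A <- mean_field_adjust(H, s2, 2)
  expect_equal(A[1, ], H[1, ] / sqrt(3))
  expect_equal(A[2, ], H[2, ] / sqrt(9))
  expect_error(mean_field_adjust(1, -1, 1))
})

test_that("threshold calibration maximizes OOD F1 over all cut points", {
  # perfectly separated: threshold in the gap, F1 = 1
  cal <- calibrate_threshold(c(0.1, 0.2, 0.8, 0.9),
                             c(FALSE, FALSE, TRUE, TRUE))
  expect_gt(cal$threshold, 0.2)
  expect_lt(cal$threshold, 0.8)
  expect_equal(cal$f1, 1)
  # hand-set overlap: exhaustive scan oracle
  u <- c(0.1, 0.4, 0.3, 0.9)
  lab <- c(FALSE, FALSE, TRUE, TRUE)
  cal2 <- calibrate_threshold(u, lab)
  brute <- sapply(sort(u), function(t) {
    pred <- u > t
    tp <- sum(pred & lab)
    if (tp == 0) return(0)
    2 * (tp / sum(pred)) * (tp / sum(lab)) /
      (tp / sum(pred) + tp / sum(lab))
  })
  expect_equal(cal2$f1, max(brute))
  # argmax property: calibrated F1 beats any quantile threshold
  set.seed(3)
  u3 <- c(rbeta(50, 2, 5), rbeta(50, 5, 2))
  lab3 <- rep(c(FALSE, TRUE), each = 50)
  cal3 <- calibrate_threshold(u3, lab3)
  f1_at <- function(t) {
    pred <- u3 > t
    tp <- sum(pred & lab3)
    if (tp == 0) return(0)
    2 * (tp / sum(pred)) * (tp / sum(lab3)) /
      (tp / sum(pred) + tp / sum(lab3))
  }
  for (q in seq(0.1, 0.9, 0.1)) {
    expect_gte(cal3$f1, f1_at(quantile(u3, q)))
  }
  expect_error(calibrate_threshold(rep(0.5, 4), c(TRUE, TRUE, FALSE, FALSE)),
               "degenerate")
})

test_that("SNGP matches the plain classifier in-distribution and is
          distance-aware", {
  set.seed(4)
  centers <- rbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0), c = c(0, 0, 1, 1))
  n <- 40
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n * 4, 0, 0.15), n) + matrix(centers[k, ], n, 4,
                                              byrow = TRUE)))
  y <- rep(rownames(centers), each = n)
  accs <- purrr::map_dfr(1:3, function(s) {
    m_sngp <- fit_sngp(X, y, seed = s, epochs = 40)
    m_rn <- train_resnet2(X, y, seed = s, epochs = 40)
    tibble::tibble(
      sngp = mean(predict(m_sngp, X)$pred_class == y),
      resnet = mean(predict(m_rn, X, type = "class") == y))
  })
  expect_lte(mean(accs$resnet) - mean(accs$sngp), 0.02)
  # predictive variance grows far from the data
  m <- fit_sngp(X, y, seed = 1, epochs = 40)
  near <- predict(m, X)
  far <- predict(m, matrix(rnorm(80, 0, 10 * sd(X)), 20))
  expect_gt(median(far$sigma2), median(near$sigma2))
  # refit with the same seed reproduces predictions exactly
  m2 <- fit_sngp(X, y, seed = 1, epochs = 40)
  expect_equal(predict(m, X)$u, predict(m2, X)$u, tolerance = 1e-12)
})

test_that("the OOD protocol scores oracle and degenerate uncertainties
          correctly", {
  set.seed(5)
  n <- 48
  Xa <- matrix(rnorm(n * 2, 0, 0.1), n) + 1
  Xb <- matrix(rnorm(n * 2, 0, 0.1), n) - 1
  Xo <- matrix(rnorm(n * 2, 0, 0.1), n) + matrix(c(4, -4), n, 2,
                                                 byrow = TRUE)
  X <- rbind(Xa, Xb)
  y <- rep(c("a", "b"), each = n)
  cells <- rep(1:24, each = 4)
  # oracle: u = 0 in-dist, 1 for OOD, perfect in-dist accuracy
  oracle_fit <- function(X, y, seed) structure(list(), class = "oracle_clf")
  oracle_predict <- function(m, Xq) {
    is_ood <- Xq[, 1] > 2
    tibble::tibble(pred_class = ifelse(Xq[, 1] > 0, "a", "b"),
                   u = ifelse(is_ood, 1, 0) +
                     seq_len(nrow(Xq)) * 1e-9)  # break threshold ties
  }
  res <- ood_protocol(X, cells, y, Xo, fit_fun = oracle_fit,
                      predict_fun = oracle_predict, n_folds = 3, seed = 1)
  expect_equal(res$mean_f1, 1, tolerance = 1e-9)
  # uncertainty ignored (threshold 1.0 rejects nothing): OOD F1 = 0
  truth <- c(y, rep("OOD", nrow(Xo)))
  pred <- oracle_predict(NULL, rbind(X, Xo))
  keep <- pred$pred_class  # u never exceeds a threshold of 1.0
  w <- rep(1, length(truth))
  f1s <- segclr:::weighted_f1_by_class(truth, keep, c("a", "b", "OOD"), w)
  expect_equal(unname(f1s["OOD"]), 0)
})

test_that("uncertainty localizes a merge between cells of different
          classes", {
  p <- main_pipeline()
  store <- p$store
  labels <- p$synth$labels
  ec <- emb_cols(store)
  thin_ids <- labels$segment_id[labels$class_name == "thin"]
  thick_ids <- labels$segment_id[labels$class_name == "thick"]
  trunk_id <- thin_ids[thin_ids %in% store$segment_id][1]
  branch_id <- thick_ids[thick_ids %in% store$segment_id][1]
  # train on thin + medium only; the thick class is never seen
  tr <- store$segment_id %in%
    labels$segment_id[labels$class_name != "thick"]
  y <- labels$class_name[match(store$segment_id, labels$segment_id)]
  m <- fit_sngp(as.matrix(store[tr, ec]), y[tr], seed = 2)
  # a merged segment: the thin cell's nodes (trunk) plus a thick cell's
  # nodes (wrongly agglomerated branch)
  trunk_u <- predict(m,
    as.matrix(store[store$segment_id == trunk_id, ec]))$u
  branch_u <- predict(m,
    as.matrix(store[store$segment_id == branch_id, ec]))$u
  expect_gt(median(branch_u), median(trunk_u))
})
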