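test_that("reference configuration reproduces the published parameter
          count", {
  cfg <- encoder_config_full()
  expect_identical(count_parameters(cfg), 33737824L)
})

test_that("parameter count grows strictly with base width", {
  cfg <- encoder_config_full()
  wider <- encoder_config(stem_channels = 128,
                          stage_widths = c(128, 256, 512, 1024))
  expect_gt(count_parameters(wider), count_parameters(cfg))
})

test_that("toy encoder builds, runs, and counts match the allocation", {
  cfg <- encoder_config_toy()
  enc <- build_encoder(cfg, seed = 1)
  expect_identical(enc$n_params, count_parameters(cfg))
  x <- array(rnorm(33^3 * 3), c(33, 33, 33, 1, 3))
  fw <- segclr:::encoder_fw(enc, x, training = FALSE, project = TRUE)
  expect_equal(dim(fw$embedding), c(3, 64))
  expect_equal(dim(fw$projection), c(3, 16))
  expect_true(all(is.finite(fw$embedding)))
})

test_that("end-to-end encoder gradients agree with finite differences", {
  tiny <- encoder_config(view_size = 9, stem_channels = 3, stem_kernel = 3,
                         stem_stride = 1, stem_pool = FALSE,
                         stage_widths = c(3, 4), blocks_per_stage = c(1, 1),
                         stage_strides = c(1, 2),
                         bottleneck_widths = c(5, 5, 6),
                         projection_widths = c(5, 5, 4))
  enc <- build_encoder(tiny, seed = 3)
  set.seed(8)
  x <- array(rnorm(9^3 * 4), c(9, 9, 9, 1, 4))
  lossfn <- function(e) {
    f <- segclr:::encoder_fw(e, x, training = TRUE, project = TRUE)
    segclr:::nt_xent_with_grad(f$projection, 0.2)$loss +
      decorrelation_loss(f$embedding)
  }
  fw <- segclr:::encoder_fw(enc, x, training = TRUE, project = TRUE)
  nt <- segclr:::nt_xent_with_grad(fw$projection, 0.2)
  dc <- segclr:::decorrelation_with_grad(fw$embedding)
  gr <- segclr:::encoder_bw(fw$enc, fw, d_embedding = dc$grad,
                            d_projection = nt$grad)
  eps <- 1e-5
  fd <- function(mutate) {
    e2 <- enc; e2 <- mutate(e2, eps)
    e3 <- enc; e3 <- mutate(e3, -eps)
    (lossfn(e2) - lossfn(e3)) / (2 * eps)
  }
  expect_equal(
    fd(function(e, d) { e$params$stem$w[1, 5] <- e$params$stem$w[1, 5] + d; e }),
    gr$trunk$stem_w[1, 5], tolerance = 1e-4)
  expect_equal(
    fd(function(e, d) {
      e$params$stages[[2]][[1]]$conv1[2, 7] <-
        e$params$stages[[2]][[1]]$conv1[2, 7] + d; e }),
    gr$trunk$stages[[2]][[1]]$conv1[2, 7], tolerance = 1e-4)
  expect_equal(
    fd(function(e, d) {
      e$params$stages[[2]][[1]]$short_w[3, 2] <-
        e$params$stages[[2]][[1]]$short_w[3, 2] + d; e }),
    gr$trunk$stages[[2]][[1]]$short_w[3, 2], tolerance = 1e-4)
  expect_equal(
    fd(function(e, d) {
      e$params$stem$bn$beta[1] <- e$params$stem$bn$beta[1] + d; e }),
    gr$trunk$stem_bn$dbeta[1], tolerance = 1e-4)
  expect_equal(
    fd(function(e, d) {
      e$params$projection[[1]]$W[3, 1] <-
        e$params$projection[[1]]$W[3, 1] + d; e }),
    gr$projection[[1]]$W[3, 1], tolerance = 1e-4)
})

test_that("zero training steps return the initialization", {
  g <- small_synth()
  pools <- enumerate_pair_pools(g$skeletons)
  enc <- build_encoder(encoder_config_toy(), seed = 2)
  ck <- train_encoder(enc, g$volume, g$skeletons, pools, steps = 0)
  expect_identical(ck$encoder$params, enc$params)
  expect_equal(nrow(ck$trace), 0)
})

test_that("short training reduces the combined loss", {
  ck <- toy_pipeline(11L, steps = 600)$checkpoint
  first <- mean(head(ck$trace$total, 10))
  last <- mean(tail(ck$trace$total, 10))
  expect_lt(last, first)
})

test_that("checkpoint restart reproduces the loss trace", {
  g <- small_synth()
  pools <- enumerate_pair_pools(g$skeletons)
  enc <- build_encoder(encoder_config_toy(), seed = 4)
  full <- train_encoder(enc, g$volume, g$skeletons, pools, steps = 6,
                        batch_pairs = 4, seed = 42)
  half <- train_encoder(enc, g$volume, g$skeletons, pools, steps = 3,
                        batch_pairs = 4, seed = 42, schedule_steps = 6)
  resumed <- train_encoder(half, g$volume, g$skeletons, pools, steps = 3,
                           batch_pairs = 4, seed = NULL)
  expect_equal(resumed$trace$total, full$trace$total, tolerance = 1e-10)
})

test_that("embedding inference is deterministic and batch-consistent", {
  g <- small_synth()
  ck <- train_encoder(build_encoder(encoder_config_toy(), seed = 5),
                      g$volume, g$skeletons,
                      enumerate_pair_pools(g$skeletons),
                      steps = 3, batch_pairs = 4, seed = 1)
  s <- g$skeletons[[1]]
  i <- which(valid_skeleton_nodes(g$volume, s))[1:3]
  views <- purrr::map(i, function(j)
    extract_view(g$volume, c(s$nodes$x[j], s$nodes$y[j], s$nodes$z[j]),
                 s$segment_id, 33))
  e1 <- embed_views(ck, views)
  e2 <- embed_views(ck, views)
  expect_identical(e1, e2)
  expect_equal(ncol(e1), 64)
  # batch embedding equals the concatenation of single-view embeddings
  singles <- do.call(rbind, purrr::map(views, function(v)
    embed_views(ck, list(v))))
  expect_equal(e1, singles, tolerance = 1e-10)
  # shape contract
  bad <- array(0, c(17, 17, 17, 1, 1))
  expect_error(embed_views(ck, bad))
})

test_that("refinement accepts small batches and improves the probe on a
          shifted dataset", {
  main <- main_pipeline()
  # a second "dataset" with a genuine domain shift: classes share their
  # geometry and differ only by subtle texture under heavier noise
  spec2 <- tibble::tibble(
    class_name = c("tex_a", "tex_b", "tex_c"),
    radius_nm_min = 150, radius_nm_max = 250,
    branch_rate_per_um = 0.05,
    tex_mean = c(0.45, 0.50, 0.55),
    tex_contrast = 0.03,
    tex_freq_per_um = c(3, 2, 1))
  g2 <- generate_synthetic(synth_config(seed = 21, class_specs = spec2,
                                        background_noise = 0.08))
  pools2 <- enumerate_pair_pools(g2$skeletons)
  ec <- paste0("e", 0:63)
  node_probe_f1 <- function(ckpt) {
    st <- infer_embeddings(ckpt, g2$volume, g2$skeletons)
    rows <- dplyr::left_join(st, g2$labels, by = "segment_id")
    lab <- stats::setNames(g2$labels$class_name, g2$labels$segment_id)
    segs <- unique(rows$segment_id)
    set.seed(3)
    tes <- unlist(lapply(split(segs, lab[as.character(segs)]),
                         function(s) sample(s, max(1, round(length(s) / 3)))))
    tr <- !(rows$segment_id %in% tes)
    f <- train_linear(rows[tr, ec], rows$class_name[tr], seed = 3)
    macro_f1(rows$class_name[!tr],
             predict(f, rows[!tr, ec], type = "class"))
  }
  f_before <- node_probe_f1(main$checkpoint)
  deltas <- purrr::map_dbl(1:5, function(s) {
    ck2 <- refine_encoder(main$checkpoint, g2$volume, g2$skeletons, pools2,
                          steps = 150, batch_pairs = 8,
                          seed = derive_seed(21, s))
    node_probe_f1(ck2) - f_before
  })
  # refinement with batch size 8 runs without architecture change and the
  # paired comparison favours the refined checkpoint
  expect_gt(mean(deltas), 0)
  # steps = 0 refinement is the identity
  same <- refine_encoder(main$checkpoint, g2$volume, g2$skeletons, pools2,
                         steps = 0)
  expect_identical(same$encoder$params, main$checkpoint$encoder$params)
})

test_that("trained embeddings pull positives together relative to other
          segments", {
  p <- main_pipeline()
  store <- p$store
  ec <- emb_cols(store)
  Z <- as.matrix(store[, ec])
  Z <- Z / sqrt(rowSums(Z^2))
  key <- paste(store$segment_id, store$node_id)
  pp <- p$pools[paste(p$pools$segment_id, p$pools$node_a) %in% key &
                  paste(p$pools$segment_id, p$pools$node_b) %in% key, ]
  ia <- match(paste(pp$segment_id, pp$node_a), key)
  ib <- match(paste(pp$segment_id, pp$node_b), key)
  pos <- mean(rowSums(Z[ia, ] * Z[ib, ]))
  set.seed(1)
  n <- nrow(Z)
  cross <- replicate(3000, {
    i <- sample(n, 2)
    if (store$segment_id[i[1]] != store$segment_id[i[2]]) {
      sum(Z[i[1], ] * Z[i[2], ])
    } else {
      NA_real_
    }
  })
  expect_gte(pos - mean(cross, na.rm = TRUE), 0.2)
})
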