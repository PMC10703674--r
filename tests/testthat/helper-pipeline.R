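# Shared, lazily built fixtures. Heavy objects (trained encoders,
# embedding stores) are built once per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small volume for unit tests of views / stores / partners: 9 cells in a
# 96^3 box, ~1 s to generate.
small_synth <- function() {
  memo("small_synth", function() {
    generate_synthetic(synth_config(volume_shape = c(96, 96, 96),
                                    n_cells = 9,
                                    cell_path_length_um = c(4, 8),
                                    seed = 401L))
  })
}

# Full toy pipeline at the study conditions: 3-class 128^3 volume, toy
# encoder on 33^3 views, 8 positive pairs per batch.
toy_pipeline <- function(seed, steps = 250, base_lr = 0.6) {
  memo(sprintf("pipe_%d_%d", seed, steps), function() {
    g <- generate_synthetic(synth_config(seed = seed))
    pools <- enumerate_pair_pools(g$skeletons)
    enc <- build_encoder(encoder_config_toy(), seed = 1L)
    ck <- train_encoder(enc, g$volume, g$skeletons, pools, steps = steps,
                        batch_pairs = 8, base_lr = base_lr,
                        seed = derive_seed(seed, 2))
    store <- infer_embeddings(ck, g$volume, g$skeletons)
    list(synth = g, pools = pools, checkpoint = ck, store = store)
  })
}

# The long-trained reference pipeline used by representation-quality and
# downstream-protocol tests.
main_pipeline <- function() toy_pipeline(11L, steps = 600)

derive_seed <- segclr:::derive_seed

emb_cols <- function(store) grep("^e\\d+$", names(store), value = TRUE)

# Held-out-segment macro F1 of a linear probe on aggregated embeddings.
probe_f1_heldout <- function(store, synth, R_nm = 5000, split_seed = 3L) {
  agg <- aggregate_store(store, synth$skeletons, R_nm = R_nm)
  agg <- dplyr::left_join(agg, synth$labels, by = "segment_id")
  lab <- stats::setNames(synth$labels$class_name, synth$labels$segment_id)
  segs <- unique(agg$segment_id)
  set.seed(split_seed)
  test_segs <- unlist(lapply(split(segs, lab[as.character(segs)]),
                             function(s) sample(s, max(1, round(length(s) / 3)))))
  tr <- !(agg$segment_id %in% test_segs)
  ec <- emb_cols(agg)
  fit <- train_linear(agg[tr, ec], agg$class_name[tr], seed = split_seed)
  pred <- predict(fit, agg[!tr, ec], type = "class")
  macro_f1(agg$class_name[!tr], pred)
}

# Stub uncertainty models for the partner cascade: fixed per-segment
# outputs, keyed by the first embedding dimension rounded to an integer
# code (the fixture encodes which row is which via e0).
stub_model <- function(table) {
  structure(list(table = table), class = "segclr_stub_model")
}

predict.segclr_stub_model <- function(object, newdata, lambda = 2, ...) {
  code <- as.integer(round(as.matrix(newdata)[, 1]))
  out <- object$table[match(code, object$table$code), ]
  out$code <- NULL
  out
}
registerS3method("predict", "segclr_stub_model", predict.segclr_stub_model,
                 envir = asNamespace("stats"))
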