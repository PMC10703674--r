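# Deterministic stub fixture for the partner-typing cascade: each segment
# carries a constant embedding whose first dimension encodes which stub
# model row applies. Chain skeletons control r_max through their length.

partner_fixture <- function() {
  coarse <- tibble::tibble(
    code = 1:6,
    pred_class = c("excitatory", "excitatory", "glia", "inhibitory",
                   "inhibitory", "excitatory"),
    u = c(0.50, 0.10, 0.10, 0.10, 0.20, 0.30),
    excitatory = c(0.4, 0.8, 0.1, 0.1, 0.2, 0.7),
    inhibitory = c(0.3, 0.1, 0.2, 0.8, 0.7, 0.2),
    glia = c(0.3, 0.1, 0.7, 0.1, 0.1, 0.1))
  fine <- tibble::tibble(
    code = 1:6,
    pred_class = c("p23", "p23", "p23", "basket", "basket", "p23"),
    u = c(0.01, 0.20, 0.01, 0.20, 0.01, 0.01),
    basket = c(0.05, 0.1, 0.05, 0.3, 0.60, 0.05),
    martinotti = c(0.05, 0.1, 0.05, 0.3, 0.25, 0.05),
    thalamocortical = c(0.40, 0.2, 0.40, 0.1, 0.05, 0.20),
    p23 = c(0.30, 0.3, 0.30, 0.2, 0.05, 0.45),
    p4 = c(0.20, 0.3, 0.20, 0.1, 0.05, 0.25))
  groups <- partner_class_groups(inhibitory = c("basket", "martinotti"),
                                 pyramidal = c("p23", "p4"))
  list(coarse = stub_model(coarse), fine = stub_model(fine),
       groups = groups)
}

# A fake store row set + skeleton for one segment: a chain along x with
# `n_nodes` nodes 1,000 nm apart, constant embedding code.
fixture_segment <- function(segment_id, code, n_nodes, y_nm = 0) {
  nodes <- tibble::tibble(node_id = seq_len(n_nodes) + segment_id * 1000L,
                          x = (seq_len(n_nodes) - 1) * 1000,
                          y = y_nm, z = 0)
  edges <- if (n_nodes > 1) {
    tibble::tibble(from = nodes$node_id[-n_nodes], to = nodes$node_id[-1])
  } else {
    tibble::tibble(from = integer(0), to = integer(0))
  }
  skel <- skeleton(segment_id, nodes, edges)
  emb <- matrix(0, n_nodes, 4)
  emb[, 1] <- code
  colnames(emb) <- paste0("e", 0:3)
  store <- dplyr::bind_cols(
    tibble::tibble(segment_id = segment_id, node_id = nodes$node_id,
                   x = nodes$x, y = nodes$y, z = nodes$z),
    tibble::as_tibble(emb))
  list(skel = skel, store = store)
}
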