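# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths (igraph, matrix
# softmax tricks) in favour of plain loops.

# All-pairs shortest paths by Floyd-Warshall over the edge list.
oracle_all_pairs <- function(nodes, edges) {
  n <- nrow(nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- match(edges$from[r], nodes$node_id)
      j <- match(edges$to[r], nodes$node_id)
      w <- sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2 +
                  (nodes$z[i] - nodes$z[j])^2)
      D[i, j] <- min(D[i, j], w)
      D[j, i] <- min(D[j, i], w)
    }
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  dimnames(D) <- list(nodes$node_id, nodes$node_id)
  D
}

# NT-Xent by explicit loops: build the (2N)x(2N) cosine similarity matrix
# and evaluate each softmax term directly.
oracle_nt_xent <- function(P, tau) {
  n <- nrow(P)
  Z <- P
  for (i in seq_len(n)) Z[i, ] <- P[i, ] / sqrt(sum(P[i, ]^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) S[i, j] <- sum(Z[i, ] * Z[j, ])
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i %% 2 == 1) i + 1 else i - 1
    denom <- 0
    for (k in seq_len(n)) if (k != i) denom <- denom + exp(S[i, k] / tau)
    total <- total - log(exp(S[i, j] / tau) / denom)
  }
  total / n
}

# Decorrelation by the literal double sum over the correlation matrix.
oracle_decorrelation <- function(E) {
  d <- ncol(E)
  C <- suppressWarnings(stats::cor(E))
  C[!is.finite(C)] <- 0
  acc <- 0
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i != j) acc <- acc + C[i, j]^2
  }
  acc / (d^2 - d)
}

# Macro F1 from per-class one-vs-rest counts, looped.
oracle_macro_f1 <- function(truth, pred, classes) {
  f1s <- numeric(0)
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    if (tp + fp + fn == 0) next
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s <- c(f1s, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  mean(f1s)
}

# Random tree-shaped skeleton with n nodes (plus optional extra edge to
# exercise cycles) in nm coordinates.
random_skeleton <- function(n, segment_id = 1L, scale_nm = 2000,
                            add_cycle = FALSE) {
  nodes <- tibble::tibble(
    node_id = seq_len(n) * 3L,  # non-contiguous ids on purpose
    x = runif(n, 0, scale_nm), y = runif(n, 0, scale_nm),
    z = runif(n, 0, scale_nm))
  edges <- if (n > 1) {
    tibble::tibble(from = nodes$node_id[sapply(2:n, function(i)
      sample(i - 1, 1))], to = nodes$node_id[2:n])
  } else {
    tibble::tibble(from = integer(0), to = integer(0))
  }
  if (add_cycle && n >= 4) {
    edges <- rbind(edges, tibble::tibble(from = nodes$node_id[1],
                                         to = nodes$node_id[n]))
  }
  skeleton(segment_id, nodes, edges)
}

# Straight chain skeleton along x with the given edge length.
chain_skeleton <- function(n, edge_nm = 1000, segment_id = 1L) {
  nodes <- tibble::tibble(node_id = seq_len(n),
                          x = (seq_len(n) - 1) * edge_nm, y = 0, z = 0)
  edges <- if (n > 1) {
    tibble::tibble(from = seq_len(n - 1), to = 2:n)
  } else {
    tibble::tibble(from = integer(0), to = integer(0))
  }
  skeleton(segment_id, nodes, edges)
}
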