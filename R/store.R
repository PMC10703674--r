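#' Infer embeddings over all skeleton nodes of a volume
#'
#' Resamples every segment's skeleton at approximately `spacing_nm` path
#' length, extracts the masked local view at each emitted node, and runs
#' the encoder. Trivial segments (fewer than `min_voxels` voxels in the
#' segmentation) are skipped entirely, as are nodes whose center voxel is
#' not owned by the segment. The result is keyed by segment ID and XYZ nm
#' position.
#'
#' @param checkpoint A `segclr_checkpoint`.
#' @param volume A [segmented_volume()].
#' @param skeletons Named list of [skeleton()]s keyed by segment id.
#' @param spacing_nm Inference node spacing (default 1500).
#' @param min_voxels Minimum segment size in voxels (default 1000).
#' @param batch_size Views per forward pass.
#' @return An embedding store: tibble with columns `segment_id`, `node_id`,
#'   `x`, `y`, `z` (nm) and `e0` ... `e63`.
#' @export
infer_embeddings <- function(checkpoint, volume, skeletons,
                             spacing_nm = 1500, min_voxels = 1000,
                             batch_size = 16) {
  if (length(skeletons) == 0) stop("empty skeleton set")
  enc <- checkpoint$encoder
  counts <- table(volume$segmentation[volume$segmentation > 0])
  rows <- list()
  for (skel in skeletons) {
    n_vox <- counts[as.character(skel$segment_id)]
    if (is.na(n_vox) || n_vox < min_voxels) next
    nodes <- skel_resample(skel, spacing_nm)
    ok <- valid_skeleton_nodes(volume, skel)[as.character(nodes$node_id)]
    nodes <- nodes[ok, , drop = FALSE]
    if (nrow(nodes) == 0) next
    emb <- matrix(NA_real_, nrow(nodes), enc$config$embedding_dim)
    for (start in seq(1, nrow(nodes), by = batch_size)) {
      idx <- start:min(start + batch_size - 1, nrow(nodes))
      views <- purrr::map(idx, function(i)
        extract_view(volume, c(nodes$x[i], nodes$y[i], nodes$z[i]),
                     skel$segment_id, enc$config$view_size))
      emb[idx, ] <- embed_views(checkpoint, views)
    }
    colnames(emb) <- paste0("e", seq_len(ncol(emb)) - 1)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(segment_id = skel$segment_id, node_id = nodes$node_id,
                     x = nodes$x, y = nodes$y, z = nodes$z),
      tibble::as_tibble(emb))
  }
  if (length(rows) == 0) {
    emb_cols <- stats::setNames(
      rep(list(numeric(0)), enc$config$embedding_dim),
      paste0("e", seq_len(enc$config$embedding_dim) - 1))
    return(dplyr::bind_cols(
      tibble::tibble(segment_id = integer(0), node_id = integer(0),
                     x = numeric(0), y = numeric(0), z = numeric(0)),
      tibble::as_tibble(emb_cols)))
  }
  dplyr::bind_rows(rows)
}

embedding_cols <- function(store) grep("^e\\d+$", names(store), value = TRUE)

#' Aggregate embeddings in a path-length radius window
#'
#' Collects all embedding rows of the segment whose skeleton node lies
#' within path-length `R_nm` of the center node and takes the per-dimension
#' mean. `r_max_nm` is the farthest contributing node's path distance --
#' small values flag short fragments whose aggregate saw little context.
#'
#' @param store Embedding store from [infer_embeddings()].
#' @param skel The segment's [skeleton()].
#' @param center_node Node id of the window center (must have a store row).
#' @param R_nm Aggregation radius in nm.
#' @return A `segclr_aggregate`: list with `segment_id`, `center_node`,
#'   `R_nm`, `mean_vector`, `n_nodes`, `r_max_nm`.
#' @export
aggregate_embedding <- function(store, skel, center_node, R_nm) {
  seg_rows <- store[store$segment_id == skel$segment_id, ]
  if (!center_node %in% seg_rows$node_id) {
    stop("center node has no embedding row")
  }
  d <- skel_distances_from(skel, center_node)
  rows <- seg_rows[is.finite(d[as.character(seg_rows$node_id)]) &
                     d[as.character(seg_rows$node_id)] <= R_nm, ]
  ec <- embedding_cols(store)
  m <- as.matrix(rows[, ec])
  structure(list(segment_id = skel$segment_id, center_node = center_node,
                 R_nm = R_nm, mean_vector = colMeans(m),
                 n_nodes = nrow(rows),
                 r_max_nm = max(d[as.character(rows$node_id)])),
            class = "segclr_aggregate")
}

#' Aggregate every store row of a set of segments
#'
#' Convenience wrapper producing one aggregated row per embedding node
#' (each node in turn acts as the window center), the per-node input for
#' cell typing.
#'
#' @inheritParams aggregate_embedding
#' @param skeletons Named list of [skeleton()]s.
#' @return Tibble: `segment_id`, `node_id`, `n_nodes`, `r_max_nm`, and the
#'   aggregated `e*` columns.
#' @export
aggregate_store <- function(store, skeletons, R_nm) {
  ec <- embedding_cols(store)
  out <- vector("list", 0)
  for (skel in skeletons) {
    seg_rows <- store[store$segment_id == skel$segment_id, ]
    if (nrow(seg_rows) == 0) next
    D <- igraph::distances(skel$graph,
                           v = node_index(skel, seg_rows$node_id),
                           to = node_index(skel, seg_rows$node_id))
    M <- as.matrix(seg_rows[, ec])
    agg <- matrix(NA_real_, nrow(seg_rows), length(ec))
    rmax <- numeric(nrow(seg_rows))
    nn <- integer(nrow(seg_rows))
    for (i in seq_len(nrow(seg_rows))) {
      w <- which(is.finite(D[i, ]) & D[i, ] <= R_nm)
      agg[i, ] <- colMeans(M[w, , drop = FALSE])
      rmax[i] <- max(D[i, w])
      nn[i] <- length(w)
    }
    colnames(agg) <- ec
    out[[length(out) + 1]] <- dplyr::bind_cols(
      tibble::tibble(segment_id = skel$segment_id,
                     node_id = seg_rows$node_id, n_nodes = nn,
                     r_max_nm = rmax),
      tibble::as_tibble(agg))
  }
  dplyr::bind_rows(out)
}

#' Nearest embedding node of a segment in Euclidean space
#'
#' @param store Embedding store.
#' @param xyz_nm Query position (nm).
#' @param segment_id Segment to search within.
#' @return The nearest store row (ties broken by lexicographic x, y, z).
#' @export
nearest_embedding_node <- function(store, xyz_nm, segment_id) {
  rows <- store[store$segment_id == segment_id, ]
  if (nrow(rows) == 0) stop("segment absent from store: ", segment_id)
  d2 <- (rows$x - xyz_nm[1])^2 + (rows$y - xyz_nm[2])^2 +
    (rows$z - xyz_nm[3])^2
  best <- which(d2 == min(d2))
  if (length(best) > 1) {
    best <- best[order(rows$x[best], rows$y[best], rows$z[best])[1]]
  }
  rows[best, ]
}

#' Write / read an embedding store as sharded CSV
#'
#' Shard layout mirrors the released embedding format: CSV rows
#' `segment_id,x,y,z,e0,...,e63`, sharded by segment id modulo the shard
#' count. Values round-trip at float precision.
#'
#' @param store Embedding store.
#' @param dir Output directory.
#' @param n_shards Number of shards.
#' @return Invisible character vector of shard paths.
#' @export
write_embedding_shards <- function(store, dir, n_shards = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ec <- embedding_cols(store)
  paths <- character(0)
  for (sh in 0:(n_shards - 1)) {
    rows <- store[store$segment_id %% n_shards == sh, ]
    p <- file.path(dir, sprintf("shard_%05d.csv", sh))
    readr::write_csv(rows[, c("segment_id", "x", "y", "z", ec)], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_embedding_shards
#' @export
read_embedding_shards <- function(dir) {
  files <- sort(list.files(dir, pattern = "^shard_.*\\.csv$",
                           full.names = TRUE))
  purrr::map_dfr(files, readr::read_csv, show_col_types = FALSE) |>
    dplyr::arrange(.data$segment_id, .data$x, .data$y, .data$z)
}
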