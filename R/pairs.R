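#' Distance-bucket boundaries for positive-pair sampling (nm)
#' @export
pair_bucket_boundaries <- c(0, 2500, 10000, 30000, 150000)

#' Enumerate positive pairs of one skeleton into distance buckets
#'
#' Every unordered node pair of the same segment with skeleton path length
#' d in (0, 150000] nm is a candidate positive pair; pairs are sorted into
#' four half-open distance buckets (lo, hi] with boundaries 0, 2,500,
#' 10,000, 30,000 and 150,000 nm, equalizing the draw over distance scales
#' (there are many more distant pairs than close ones). Pairs at distance
#' 0 (the same node) are excluded, as are pairs beyond 150 um.
#'
#' @param skel A [skeleton()].
#' @param boundaries Bucket boundaries in nm (5 increasing values).
#' @return Tibble: `segment_id`, `node_a`, `node_b` (node_a < node_b),
#'   `distance_nm`, `bucket` (1-based index).
#' @export
enumerate_pairs <- function(skel, boundaries = pair_bucket_boundaries) {
  stopifnot(length(boundaries) >= 2, !is.unsorted(boundaries))
  empty <- tibble::tibble(segment_id = integer(0), node_a = integer(0),
                          node_b = integer(0), distance_nm = numeric(0),
                          bucket = integer(0))
  n <- nrow(skel$nodes)
  if (n < 2) return(empty)
  D <- igraph::distances(skel$graph)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  keep <- is.finite(d) & d > boundaries[1] & d <= boundaries[length(boundaries)]
  if (!any(keep)) return(empty)
  iu <- iu[keep, , drop = FALSE]
  d <- d[keep]
  ids <- skel$nodes$node_id
  a <- pmin(ids[iu[, 1]], ids[iu[, 2]])
  b <- pmax(ids[iu[, 1]], ids[iu[, 2]])
  bucket <- findInterval(d, boundaries, left.open = TRUE,
                         rightmost.closed = FALSE)
  tibble::tibble(segment_id = skel$segment_id, node_a = a, node_b = b,
                 distance_nm = d, bucket = as.integer(bucket))
}

#' Enumerate pair pools over a set of skeletons
#'
#' @param skeletons List of [skeleton()]s.
#' @inheritParams enumerate_pairs
#' @return Row-bound pair pools (see [enumerate_pairs()]).
#' @export
enumerate_pair_pools <- function(skeletons,
                                 boundaries = pair_bucket_boundaries) {
  purrr::map_dfr(skeletons, enumerate_pairs, boundaries = boundaries)
}

#' Sample a batch of positive pairs
#'
#' Draws `n_pairs` positive pairs for one training batch. Segments are
#' drawn without replacement, so the contrastive negatives for any pair
#' come from the other `n_pairs - 1` segments of the batch. Within a
#' segment, a distance bucket is chosen uniformly among that segment's
#' non-empty buckets, then a pair uniformly within the bucket.
#'
#' @param pools Pair pools from [enumerate_pair_pools()].
#' @param n_pairs Number of pairs to draw.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Tibble of `n_pairs` rows (columns as in [enumerate_pairs()]).
#' @export
sample_pair_batch <- function(pools, n_pairs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- unique(pools$segment_id)
  if (length(segs) < n_pairs) {
    stop(sprintf("need %d segments with eligible pairs, have %d",
                 n_pairs, length(segs)))
  }
  chosen <- sample(segs, n_pairs)
  purrr::map_dfr(chosen, function(sid) {
    sp <- pools[pools$segment_id == sid, ]
    bk <- sample_one(unique(sp$bucket))
    spb <- sp[sp$bucket == bk, ]
    spb[sample.int(nrow(spb), 1), ]
  })
}

# sample() with surprise-free single-element behaviour
sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1)]
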