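#' Skeleton of a segmented object
#'
#' A skeleton is a node/edge graph in physical nm coordinates summarizing a
#' segment's centerline. Path length between nodes is the sum of Euclidean
#' edge lengths along the shortest edge path (arc length along the
#' skeleton). Multi-component skeletons are allowed; nodes in different
#' components are at infinite path distance.
#'
#' @param segment_id Integer segment ID the skeleton belongs to.
#' @param nodes Tibble/data frame with columns `node_id`, `x`, `y`, `z`
#'   (nm). Optional extra columns (e.g. `radius_nm`, `subcompartment`) are
#'   kept.
#' @param edges Tibble/data frame with columns `from`, `to` (node ids).
#' @return A `segclr_skeleton` object.
#' @export
skeleton <- function(segment_id, nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("node_id", "x", "y", "z") %in% names(nodes)))
  if (anyDuplicated(nodes$node_id)) stop("node_ids must be unique")
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    bad <- !(edges$from %in% nodes$node_id) | !(edges$to %in% nodes$node_id)
    if (any(bad)) stop("edge endpoints must be node ids")
  }
  obj <- structure(
    list(segment_id = segment_id, nodes = nodes, edges = edges),
    class = "segclr_skeleton"
  )
  obj$graph <- skeleton_graph(obj)
  obj
}

# Build the weighted igraph representation (weights = Euclidean nm length).
skeleton_graph <- function(skel) {
  n <- skel$nodes
  ids <- as.character(n$node_id)
  g <- igraph::make_empty_graph(n = nrow(n), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(skel$edges) > 0) {
    ai <- match(skel$edges$from, n$node_id)
    bi <- match(skel$edges$to, n$node_id)
    w <- sqrt((n$x[ai] - n$x[bi])^2 + (n$y[ai] - n$y[bi])^2 +
                (n$z[ai] - n$z[bi])^2)
    if (any(w <= 0)) stop("edge lengths must be > 0")
    g <- igraph::add_edges(g, rbind(ai, bi), weight = w)
  }
  g
}

#' @export
print.segclr_skeleton <- function(x, ...) {
  cat(sprintf("<segclr_skeleton> segment %s: %d nodes, %d edges\n",
              x$segment_id, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

node_index <- function(skel, node_id) {
  i <- match(node_id, skel$nodes$node_id)
  if (any(is.na(i))) stop("unknown node id: ",
                          paste(node_id[is.na(i)], collapse = ", "))
  i
}

#' Path length between two skeleton nodes
#'
#' Shortest-path distance along the skeleton (Dijkstra with Euclidean nm
#' edge weights). Returns `Inf` for nodes in different components.
#'
#' @param skel A [skeleton()].
#' @param node_a,node_b Node ids.
#' @return Path length in nm (0 for identical nodes).
#' @export
skel_path_length <- function(skel, node_a, node_b) {
  ia <- node_index(skel, node_a)
  ib <- node_index(skel, node_b)
  as.numeric(igraph::distances(skel$graph, v = ia, to = ib))
}

# All path lengths from one node, as a named numeric vector over node_ids.
skel_distances_from <- function(skel, node_id) {
  i <- node_index(skel, node_id)
  d <- as.numeric(igraph::distances(skel$graph, v = i))
  names(d) <- skel$nodes$node_id
  d
}

#' Resample skeleton nodes at a fixed path-length spacing
#'
#' Greedy traversal: from the root of each connected component (the lowest
#' node id, a deterministic choice), walk the skeleton depth-first and emit
#' a node whenever the accumulated path length since the last emitted node
#' on that path reaches the spacing. The root itself is always emitted, so
#' every node lies within `spacing_nm` (along the path) of an emitted node.
#' This is the node set used for embedding inference, where views at
#' roughly 1,500 nm spacing give substantially overlapping fields of view.
#'
#' @param skel A [skeleton()].
#' @param spacing_nm Target path-length spacing in nm (default 1500).
#' @return Tibble of emitted nodes (subset of `skel$nodes` rows) with an
#'   extra column `path_offset_nm`, the distance from the component root at
#'   which each node was emitted.
#' @export
skel_resample <- function(skel, spacing_nm = 1500) {
  stopifnot(spacing_nm > 0)
  g <- skel$graph
  n <- nrow(skel$nodes)
  if (n == 0) return(skel$nodes[0, ])
  comp <- igraph::components(g)$membership
  emitted <- integer(0)
  offsets <- numeric(0)
  for (cm in sort(unique(comp))) {
    verts <- which(comp == cm)
    root <- verts[which.min(skel$nodes$node_id[verts])]
    # iterative DFS carrying distance-since-last-emission
    adj <- igraph::adjacent_vertices(g, verts)
    names(adj) <- as.character(verts)
    visited <- rep(FALSE, n)
    stack <- list(list(v = root, since = 0, dist = 0))
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- fr$v
      if (visited[v]) next
      visited[v] <- TRUE
      since <- fr$since
      if (v == root || since >= spacing_nm) {
        emitted <- c(emitted, v)
        offsets <- c(offsets, fr$dist)
        since <- 0
      }
      nbrs <- as.integer(adj[[as.character(v)]])
      nbrs <- nbrs[!visited[nbrs]]
      # deterministic order: descending id so lowest id is expanded first
      for (w in nbrs[order(skel$nodes$node_id[nbrs], decreasing = TRUE)]) {
        ew <- sqrt(sum((skel$nodes[w, c("x", "y", "z")] -
                          skel$nodes[v, c("x", "y", "z")])^2))
        stack[[length(stack) + 1]] <- list(v = w, since = since + ew,
                                           dist = fr$dist + ew)
      }
    }
  }
  out <- skel$nodes[emitted, , drop = FALSE]
  out$path_offset_nm <- offsets
  out
}

#' Collect all nodes within a path-length radius
#'
#' The radius window around a center node contains every node whose
#' path-length distance is at most `R_nm`; `r_max_nm` records the farthest
#' collected node's distance (the basis of the short-fragment filter in
#' synaptic partner typing).
#'
#' @param skel A [skeleton()].
#' @param center Node id of the window center.
#' @param R_nm Path-length radius in nm (>= 0).
#' @return A list of class `segclr_radius_window` with fields `center`,
#'   `node_ids`, `distances_nm`, `R_nm`, `r_max_nm`.
#' @export
skel_radius_window <- function(skel, center, R_nm) {
  stopifnot(R_nm >= 0)
  d <- skel_distances_from(skel, center)
  keep <- which(is.finite(d) & d <= R_nm)
  structure(
    list(center = center,
         node_ids = skel$nodes$node_id[keep],
         distances_nm = unname(d[keep]),
         R_nm = R_nm,
         r_max_nm = if (length(keep)) max(d[keep]) else 0),
    class = "segclr_radius_window"
  )
}

#' @export
print.segclr_radius_window <- function(x, ...) {
  cat(sprintf("<radius window> center %s: %d nodes, R = %g nm, R_max = %g nm\n",
              x$center, length(x$node_ids), x$R_nm, x$r_max_nm))
  invisible(x)
}

#' Read a skeleton from an SWC file
#'
#' SWC columns: node_id, type, x, y, z, radius, parent_id (-1 for roots).
#' Coordinates and radii are in nm. The SWC `type` code is carried through
#' as an integer column `swc_type`.
#'
#' @param path File path.
#' @param segment_id Segment id to attach (default: parsed from filename).
#' @return A [skeleton()].
#' @export
read_swc <- function(path, segment_id = NULL) {
  if (is.null(segment_id)) {
    segment_id <- suppressWarnings(
      as.integer(gsub("\\D", "", basename(path))))
  }
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("node_id", "swc_type", "x", "y",
                                         "z", "radius_nm", "parent"))
  edges <- tab[tab$parent >= 0, c("parent", "node_id")]
  names(edges) <- c("from", "to")
  skeleton(segment_id,
           tab[, c("node_id", "x", "y", "z", "radius_nm", "swc_type")],
           edges)
}

#' Write a skeleton to an SWC file
#'
#' @param skel A [skeleton()]. Must be a forest (acyclic) for SWC's
#'   parent-pointer encoding; roots get parent -1.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  n <- skel$nodes
  parent <- rep(-1L, nrow(n))
  if (nrow(skel$edges) > 0) {
    # orient edges away from each component root via BFS
    g <- skel$graph
    comp <- igraph::components(g)$membership
    for (cm in unique(comp)) {
      verts <- which(comp == cm)
      root <- verts[which.min(n$node_id[verts])]
      bfs <- igraph::bfs(g, root = root, father = TRUE,
                         unreachable = FALSE)
      fa <- as.integer(bfs$father)
      reached <- !is.na(fa) & fa > 0
      parent[reached] <- n$node_id[fa[reached]]
    }
  }
  rad <- if ("radius_nm" %in% names(n)) n$radius_nm else rep(1, nrow(n))
  typ <- if ("swc_type" %in% names(n)) n$swc_type else rep(0L, nrow(n))
  lines <- sprintf("%d %d %.3f %.3f %.3f %.3f %d",
                   n$node_id, typ, n$x, n$y, n$z, rad, parent)
  writeLines(c("# SWC skeleton (coordinates in nm)", lines), path)
  invisible(path)
}
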