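#' Configuration for the synthetic segmented-volume generator
#'
#' The generator emulates a small segmented electron-microscopy volume:
#' several tubular, optionally branched "cells" from a few morphological
#' classes are grown as persistent random walks, rasterized by sphere
#' sweeping into a dense instance segmentation, and textured with
#' class-specific intensity statistics on a noisy background. The exact
#' generating centerline becomes the ground-truth skeleton, and synthetic
#' synapses are placed where two segments touch.
#'
#' Class specs distinguish classes by tube radius, branching rate and
#' intensity texture (mean / contrast / spatial frequency), so a
#' per-segment mean-intensity readout already separates classes; the
#' contrastive encoder has both texture and shape cues available.
#'
#' @param volume_shape Integer vector of 3 voxel counts.
#' @param voxel_size_nm Numeric vector of 3 voxel edge lengths in nm;
#'   anisotropy is honoured throughout (default mirrors common serial
#'   section EM resolution, 32 x 32 x 40 nm).
#' @param n_cells Number of cells to place (round-robin over classes).
#' @param class_specs Tibble with columns `class_name`, `radius_nm_min`,
#'   `radius_nm_max`, `branch_rate_per_um`, `tex_mean`, `tex_contrast`,
#'   `tex_freq_per_um`.
#' @param background_noise Intensity s.d. of the background (mean 0.45).
#' @param synapse_density_per_um Expected synapses per um of skeleton path.
#' @param cell_path_length_um Range (min, max) of total centerline length
#'   per cell, in um.
#' @param node_spacing_nm Skeleton node spacing along the centerline.
#' @param soma Logical; grow a thick blob-like region at each cell root so
#'   that per-node radius regimes (thin / medium / thick) give a
#'   within-cell subcompartment labeling.
#' @param seed Integer seed; fully determines the output.
#' @return A `segclr_synth_config` list.
#' @export
synth_config <- function(volume_shape = c(128, 128, 128),
                         voxel_size_nm = c(32, 32, 40),
                         n_cells = 18,
                         class_specs = default_class_specs(),
                         background_noise = 0.04,
                         synapse_density_per_um = 0.25,
                         cell_path_length_um = c(6, 12),
                         node_spacing_nm = 250,
                         soma = TRUE,
                         seed = 1L) {
  stopifnot(length(volume_shape) == 3, all(volume_shape > 0),
            length(voxel_size_nm) == 3, all(voxel_size_nm > 0),
            n_cells >= 0, nrow(class_specs) >= 1)
  if (any(class_specs$radius_nm_min < min(voxel_size_nm)))
    stop("class radii must be at least one voxel")
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 n_cells = as.integer(n_cells),
                 class_specs = tibble::as_tibble(class_specs),
                 background_noise = background_noise,
                 synapse_density_per_um = synapse_density_per_um,
                 cell_path_length_um = cell_path_length_um,
                 node_spacing_nm = node_spacing_nm,
                 soma = soma,
                 seed = as.integer(seed)),
            class = "segclr_synth_config")
}

#' Default synthetic cell classes
#'
#' Three classes separated jointly by caliber and texture: a thin
#' axon-like class, a medium dendrite-like class and a thick glia-like
#' class. Texture means are disjoint so the mean-intensity separability
#' floor holds by construction.
#' @return Tibble of class specs (see [synth_config()]).
#' @export
default_class_specs <- function() {
  tibble::tibble(
    class_name = c("thin", "medium", "thick"),
    radius_nm_min = c(64, 160, 300),
    radius_nm_max = c(96, 240, 400),
    branch_rate_per_um = c(0.05, 0.08, 0.03),
    tex_mean = c(0.30, 0.55, 0.80),
    tex_contrast = c(0.06, 0.06, 0.06),
    tex_freq_per_um = c(4, 2, 1)
  )
}

#' Segmented volume container
#'
#' @param intensity 3D numeric array of intensities in `[0, 1]`.
#' @param segmentation 3D integer array of instance IDs (0 = background).
#' @param voxel_size_nm Numeric vector of 3 voxel edge lengths in nm.
#' @return A `segclr_volume` object.
#' @export
segmented_volume <- function(intensity, segmentation, voxel_size_nm) {
  stopifnot(identical(dim(intensity), dim(segmentation)),
            length(voxel_size_nm) == 3)
  structure(list(intensity = intensity,
                 segmentation = segmentation,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 intensity_mean = mean(intensity)),
            class = "segclr_volume")
}

#' @export
print.segclr_volume <- function(x, ...) {
  cat(sprintf("<segclr_volume> %s voxels @ %s nm, %d segments\n",
              paste(dim(x$intensity), collapse = "x"),
              paste(x$voxel_size_nm, collapse = "x"),
              length(setdiff(unique(as.vector(x$segmentation)), 0L))))
  invisible(x)
}

# Subcompartment label from the local tube radius (nm).
radius_regime <- function(radius_nm) {
  cut(radius_nm, breaks = c(-Inf, 120, 280, Inf),
      labels = c("axon_like", "dendrite_like", "soma_like"),
      right = TRUE) |> as.character()
}

# Persistent random walk with branching, confined to the box (nm).
# Returns a tibble of nodes (node_id, x, y, z, radius_nm, parent) where
# parent = 0 marks the root, plus a dense sampling for rasterization.
grow_cell <- function(cfg, spec, seg, next_node_id) {
  box_nm <- cfg$volume_shape * cfg$voxel_size_nm
  base_r <- runif(1, spec$radius_nm_min, spec$radius_nm_max)
  soma_r <- if (cfg$soma) min(2.2 * base_r, 500) else base_r
  root_margin <- soma_r + max(cfg$voxel_size_nm)
  margin <- base_r * 1.3 + max(cfg$voxel_size_nm)
  if (any(box_nm <= 2 * root_margin)) {
    stop(structure(
      list(message = "volume too small for the cell radius and soma margin",
           call = NULL),
      class = c("segclr_placement_error", "error", "condition")))
  }
  vox_at <- function(p) {
    v <- pmin(pmax(floor(p / cfg$voxel_size_nm), 0), cfg$volume_shape - 1)
    seg[1 + v[1] + cfg$volume_shape[1] * (v[2] + cfg$volume_shape[2] * v[3])]
  }
  # root placement on free voxels, bounded retries
  root <- NULL
  for (try in seq_len(200)) {
    p <- root_margin + runif(3) * (box_nm - 2 * root_margin)
    if (vox_at(p) == 0L) { root <- p; break }
  }
  if (is.null(root)) {
    cond <- structure(
      list(message = "could not place cell root: volume too crowded or too small",
           call = NULL),
      class = c("segclr_placement_error", "error", "condition"))
    stop(cond)
  }
  budget <- runif(1, cfg$cell_path_length_um[1],
                  cfg$cell_path_length_um[2]) * 1000
  step <- cfg$node_spacing_nm
  soma_len <- if (cfg$soma) 600 else -1
  rad_at <- function(arc) {
    if (arc <= soma_len) soma_r else
      base_r * (1 + 0.15 * sin(arc / 2000))
  }
  rand_dir <- function() {
    d <- rnorm(3); d / sqrt(sum(d^2))
  }
  nodes <- list()
  nid <- next_node_id
  add_node <- function(p, r, parent) {
    nodes[[length(nodes) + 1]] <<- c(nid, p, r, parent)
    nid <<- nid + 1L
    nid - 1L
  }
  root_id <- add_node(root, rad_at(0), 0L)
  tips <- list(list(p = root, dir = rand_dir(), node = root_id, arc = 0))
  used <- 0
  while (used < budget && length(tips) > 0) {
    new_tips <- list()
    for (tip in tips) {
      if (used >= budget) break
      ok <- FALSE
      dir <- tip$dir
      for (att in seq_len(8)) {
        cand_dir <- dir + 0.35 * rnorm(3)
        cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
        cand <- tip$p + step * cand_dir
        inside <- all(cand > margin) && all(cand < box_nm - margin)
        if (inside && vox_at(cand) == 0L) { ok <- TRUE; break }
        dir <- rand_dir()  # deflect and retry
      }
      if (!ok) next  # branch terminates against a wall or another cell
      arc <- tip$arc + step
      id <- add_node(cand, rad_at(arc), tip$node)
      used <- used + step
      new_tips[[length(new_tips) + 1]] <-
        list(p = cand, dir = cand_dir, node = id, arc = arc)
      if (runif(1) < spec$branch_rate_per_um * step / 1000) {
        bd <- cand_dir + rnorm(3)
        new_tips[[length(new_tips) + 1]] <-
          list(p = cand, dir = bd / sqrt(sum(bd^2)), node = id, arc = arc)
      }
    }
    if (length(new_tips) == 0) break
    tips <- new_tips
  }
  m <- do.call(rbind, nodes)
  tibble::tibble(node_id = as.integer(m[, 1]), x = m[, 2], y = m[, 3],
                 z = m[, 4], radius_nm = m[, 5], parent = as.integer(m[, 6]))
}

# Dense sphere sampling along every edge for rasterization.
sweep_samples <- function(nodes, step_nm) {
  kids <- nodes[nodes$parent > 0, ]
  if (nrow(kids) == 0) {
    return(list(centers = as.matrix(nodes[, c("x", "y", "z")]),
                radii = nodes$radius_nm))
  }
  pi_ <- match(kids$parent, nodes$node_id)
  centers <- list(as.matrix(nodes[, c("x", "y", "z")]))
  radii <- list(nodes$radius_nm)
  for (i in seq_len(nrow(kids))) {
    a <- as.numeric(nodes[pi_[i], c("x", "y", "z")])
    b <- as.numeric(kids[i, c("x", "y", "z")])
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, by = min(1, step_nm / max(len, 1e-9)))
    centers[[length(centers) + 1]] <-
      cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]),
            a[3] + ts * (b[3] - a[3]))
    radii[[length(radii) + 1]] <-
      nodes$radius_nm[pi_[i]] + ts * (kids$radius_nm[i] - nodes$radius_nm[pi_[i]])
  }
  list(centers = do.call(rbind, centers), radii = unlist(radii))
}

#' Generate a synthetic segmented volume with skeletons, labels and synapses
#'
#' Runs the full generator: grows each cell as a persistent random walk
#' (round-robin over classes), rasterizes tubes by sphere sweeping with
#' first-writer-wins voxel collisions, textures each segment from its class
#' intensity statistics, derives the exact skeleton from the generating
#' centerline, assigns per-node subcompartment labels by local radius
#' regime, and places synapses at sampled contact points between segments.
#'
#' @param config A [synth_config()].
#' @return A `segclr_synth` list: `volume` ([segmented_volume()]),
#'   `skeletons` (named list of [skeleton()]s keyed by segment id),
#'   `labels` (tibble segment_id, class_name), `node_labels` (tibble
#'   segment_id, node_id, subcompartment), `synapses` (tibble synapse_id,
#'   pre_segment_id, post_segment_id, x, y, z), `collisions` (voxel
#'   collision count), and the `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "segclr_synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  shape <- config$volume_shape
  seg <- array(0L, dim = shape)
  specs <- config$class_specs
  labels <- tibble::tibble(segment_id = integer(0), class_name = character(0))
  skeletons <- list()
  collisions <- 0L
  next_node <- 1L
  raster_step <- min(config$voxel_size_nm) / 2

  for (i in seq_len(config$n_cells)) {
    spec <- specs[((i - 1) %% nrow(specs)) + 1, ]
    nodes <- grow_cell(config, spec, seg, next_node)
    next_node <- max(nodes$node_id) + 1L
    sw <- sweep_samples(nodes, raster_step)
    collisions <- collisions +
      raster_spheres_cpp(seg, config$voxel_size_nm, sw$centers, sw$radii, i)
    edges <- nodes[nodes$parent > 0, c("parent", "node_id")]
    names(edges) <- c("from", "to")
    nd <- nodes[, c("node_id", "x", "y", "z", "radius_nm")]
    nd$subcompartment <- radius_regime(nd$radius_nm)
    skeletons[[as.character(i)]] <- skeleton(i, nd, edges)
    labels <- dplyr::bind_rows(labels,
      tibble::tibble(segment_id = i, class_name = spec$class_name))
  }

  intensity <- synth_intensity(seg, labels, specs, config)
  vol <- segmented_volume(intensity, seg, config$voxel_size_nm)
  node_labels <- purrr::map_dfr(skeletons, function(s)
    tibble::tibble(segment_id = s$segment_id, node_id = s$nodes$node_id,
                   subcompartment = s$nodes$subcompartment))
  synapses <- place_synapses(vol, skeletons, config)

  structure(list(volume = vol, skeletons = skeletons, labels = labels,
                 node_labels = node_labels, synapses = synapses,
                 collisions = collisions, config = config),
            class = "segclr_synth")
}

# Class-specific texture: mean + contrast * sinusoid along a random
# direction (frequency in cycles per um) + voxel noise; background is
# plain Gaussian noise around 0.45. Everything clamped to [0, 1].
synth_intensity <- function(seg, labels, specs, config) {
  shape <- dim(seg)
  intensity <- array(rnorm(length(seg), 0.45, config$background_noise),
                     dim = shape)
  if (nrow(labels) > 0) {
    # voxel center coordinates in nm, computed lazily per segment
    for (sid in labels$segment_id) {
      idx <- which(seg == sid)
      if (length(idx) == 0) next
      spec <- specs[specs$class_name ==
                      labels$class_name[labels$segment_id == sid], ][1, ]
      i0 <- idx - 1L
      vx <- (i0 %% shape[1] + 0.5) * config$voxel_size_nm[1]
      rem <- i0 %/% shape[1]
      vy <- (rem %% shape[2] + 0.5) * config$voxel_size_nm[2]
      vz <- (rem %/% shape[2] + 0.5) * config$voxel_size_nm[3]
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      phase <- runif(1, 0, 2 * pi)
      tex <- sin(2 * pi * spec$tex_freq_per_um *
                   (vx * u[1] + vy * u[2] + vz * u[3]) / 1000 + phase)
      intensity[idx] <- spec$tex_mean + spec$tex_contrast * tex +
        rnorm(length(idx), 0, 0.02)
    }
  }
  pmin(pmax(intensity, 0), 1)
}

# Sample synapses where two segments come within ~2 voxels of each other:
# ray-march outward from skeleton nodes and record the first foreign
# segment hit just beyond the tube surface.
place_synapses <- function(vol, skeletons, config) {
  out <- list()
  shape <- dim(vol$segmentation)
  vs <- vol$voxel_size_nm
  seg_at <- function(p) {
    v <- floor(p / vs)
    if (any(v < 0) || any(v >= shape)) return(NA_integer_)
    vol$segmentation[1 + v[1] + shape[1] * (v[2] + shape[2] * v[3])]
  }
  syn_id <- 0L
  for (s in skeletons) {
    n <- s$nodes
    if (nrow(n) < 2) next
    path_um <- sum_edge_length(s) / 1000
    n_syn <- stats::rpois(1, config$synapse_density_per_um * path_um)
    placed <- 0L
    tries <- 0L
    while (placed < n_syn && tries < n_syn * 25) {
      tries <- tries + 1L
      j <- sample.int(nrow(n), 1)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p0 <- as.numeric(n[j, c("x", "y", "z")])
      reach <- n$radius_nm[j] + 2.5 * max(vs)
      for (t in seq(min(vs) / 2, reach, by = min(vs) / 2)) {
        id <- seg_at(p0 + t * dir)
        if (is.na(id)) break
        if (id != 0L && id != s$segment_id) {
          syn_id <- syn_id + 1L
          p <- p0 + t * dir
          out[[length(out) + 1]] <- tibble::tibble(
            synapse_id = syn_id, pre_segment_id = s$segment_id,
            post_segment_id = id, x = p[1], y = p[2], z = p[3])
          placed <- placed + 1L
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(synapse_id = integer(0), pre_segment_id = integer(0),
                          post_segment_id = integer(0), x = numeric(0),
                          y = numeric(0), z = numeric(0)))
  }
  dplyr::bind_rows(out)
}

sum_edge_length <- function(skel) {
  if (nrow(skel$edges) == 0) return(0)
  a <- match(skel$edges$from, skel$nodes$node_id)
  b <- match(skel$edges$to, skel$nodes$node_id)
  sum(sqrt((skel$nodes$x[a] - skel$nodes$x[b])^2 +
             (skel$nodes$y[a] - skel$nodes$y[b])^2 +
             (skel$nodes$z[a] - skel$nodes$z[b])^2))
}

#' @export
print.segclr_synth <- function(x, ...) {
  cat(sprintf(paste0("<segclr_synth> %d cells, %d synapses, %d voxel ",
                     "collisions (seed %d)\n"),
              nrow(x$labels), nrow(x$synapses), x$collisions, x$config$seed))
  invisible(x)
}
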