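#' Default thresholds of the partner-typing cascade
#'
#' `r_max_min_nm`: minimum furthest-aggregation distance (fragments below
#' are too short to type); `u_coarse_max`: maximum coarse 3-class
#' uncertainty; `u_fine_max`: maximum subtype uncertainty.
#' @export
partner_thresholds <- function(r_max_min_nm = 2500, u_coarse_max = 0.45,
                               u_fine_max = 0.05) {
  list(r_max_min_nm = r_max_min_nm, u_coarse_max = u_coarse_max,
       u_fine_max = u_fine_max)
}

#' Class metadata for the subtype model
#'
#' @param inhibitory Subtype names belonging to the inhibitory group.
#' @param pyramidal Subtype names of the pyramidal (excitatory) group.
#' @param thalamocortical Name of the thalamocortical class.
#' @export
partner_class_groups <- function(inhibitory, pyramidal,
                                 thalamocortical = "thalamocortical") {
  list(inhibitory = inhibitory, pyramidal = pyramidal,
       thalamocortical = thalamocortical)
}

#' Type one fragment through the uncertainty cascade
#'
#' The cascade, in order: (1) fragments with furthest aggregation
#' distance below 2.5 um are labeled `UNC` (too short); (2) coarse
#' 3-class (excitatory / inhibitory / glia) uncertainty above 0.45 gives
#' `UNC`; (3) a glia coarse call gives `UNC` (glia do not form the
#' synapses under analysis); (4) inhibitory fragments with subtype
#' uncertainty below 0.05 get the highest-probability inhibitory subtype,
#' otherwise `I-UNC`; (5) excitatory fragments with subtype uncertainty
#' below 0.05 get the thalamocortical label when its probability exceeds
#' the summed pyramidal subtype probabilities and the best pyramidal
#' subtype otherwise; excitatory fragments above the subtype uncertainty
#' give `P-UNC`.
#'
#' @param agg A `segclr_aggregate` (from [aggregate_embedding()]).
#' @param coarse_model 3-class model (classes excitatory / inhibitory /
#'   glia) whose `predict` returns `pred_class`, `u` and probability
#'   columns.
#' @param fine_model Subtype model (same predict contract).
#' @param groups Class metadata from [partner_class_groups()].
#' @param thresholds From [partner_thresholds()].
#' @param lambda Mean-field coefficient for adjusted logits (default 2).
#' @return One-row tibble: `label`, `stage`, `u_coarse`, `u_fine`,
#'   `r_max_nm`.
#' @export
classify_fragment <- function(agg, coarse_model, fine_model, groups,
                              thresholds = partner_thresholds(),
                              lambda = 2) {
  if (is.null(coarse_model)) stop("missing coarse model")
  row <- function(label, stage, u_coarse = NA_real_, u_fine = NA_real_) {
    tibble::tibble(label = label, stage = stage, u_coarse = u_coarse,
                   u_fine = u_fine, r_max_nm = agg$r_max_nm)
  }
  if (agg$r_max_nm < thresholds$r_max_min_nm) {
    return(row("UNC", "short_fragment"))
  }
  X <- matrix(agg$mean_vector, nrow = 1)
  pc <- predict(coarse_model, X, lambda = lambda)
  if (pc$u[1] > thresholds$u_coarse_max) {
    return(row("UNC", "uncertain_coarse", u_coarse = pc$u[1]))
  }
  if (pc$pred_class[1] == "glia") {
    return(row("UNC", "glia", u_coarse = pc$u[1]))
  }
  if (is.null(fine_model)) stop("missing fine model")
  pf <- predict(fine_model, X, lambda = lambda)
  u_fine <- pf$u[1]
  if (pc$pred_class[1] == "inhibitory") {
    if (u_fine >= thresholds$u_fine_max) {
      return(row("I-UNC", "uncertain_inhibitory_subtype", pc$u[1], u_fine))
    }
    probs <- unlist(pf[1, groups$inhibitory])
    return(row(names(probs)[which.max(probs)], "inhibitory_subtype",
               pc$u[1], u_fine))
  }
  # excitatory
  if (u_fine >= thresholds$u_fine_max) {
    return(row("P-UNC", "uncertain_excitatory_subtype", pc$u[1], u_fine))
  }
  p_tc <- pf[[groups$thalamocortical]][1]
  p_pyr <- unlist(pf[1, groups$pyramidal])
  if (p_tc > sum(p_pyr)) {
    return(row(groups$thalamocortical, "thalamocortical", pc$u[1], u_fine))
  }
  row(names(p_pyr)[which.max(p_pyr)], "pyramidal_subtype", pc$u[1], u_fine)
}

#' Type the partners of a synapse table
#'
#' For every synapse and side (pre/post): find the segment's nearest
#' embedding node in Euclidean space, aggregate at 25 um along the
#' skeleton, and run the uncertainty cascade. Sides whose segment has no
#' embedding rows become `UNC` (stage `no_embedding`). No synapse is
#' dropped: the output has exactly one row per input synapse.
#'
#' @param synapses Tibble with `synapse_id`, `pre_segment_id`,
#'   `post_segment_id`, `x`, `y`, `z` (nm).
#' @param store Embedding store from [infer_embeddings()].
#' @param skeletons Named list of [skeleton()]s.
#' @param coarse_model,fine_model,groups,thresholds,lambda See
#'   [classify_fragment()].
#' @param R_nm Aggregation radius (default 25,000 nm).
#' @return List: `typed` (tibble: synapse_id, pre/post labels, stages,
#'   uncertainties, r_max), `report` (per-side counts and fractions by
#'   cascade stage).
#' @export
type_synapses <- function(synapses, store, skeletons, coarse_model,
                          fine_model, groups,
                          thresholds = partner_thresholds(),
                          lambda = 2, R_nm = 25000) {
  if (nrow(synapses) == 0) stop("empty synapse table")
  one_side <- function(seg_id, xyz) {
    if (!seg_id %in% store$segment_id) {
      return(tibble::tibble(label = "UNC", stage = "no_embedding",
                            u_coarse = NA_real_, u_fine = NA_real_,
                            r_max_nm = NA_real_))
    }
    nn <- nearest_embedding_node(store, xyz, seg_id)
    agg <- aggregate_embedding(store, skeletons[[as.character(seg_id)]],
                               nn$node_id, R_nm)
    classify_fragment(agg, coarse_model, fine_model, groups, thresholds,
                      lambda)
  }
  rows <- purrr::map_dfr(seq_len(nrow(synapses)), function(i) {
    xyz <- c(synapses$x[i], synapses$y[i], synapses$z[i])
    pre <- one_side(synapses$pre_segment_id[i], xyz)
    post <- one_side(synapses$post_segment_id[i], xyz)
    tibble::tibble(synapse_id = synapses$synapse_id[i],
                   pre_segment_id = synapses$pre_segment_id[i],
                   post_segment_id = synapses$post_segment_id[i],
                   x = synapses$x[i], y = synapses$y[i], z = synapses$z[i],
                   pre_label = pre$label, pre_stage = pre$stage,
                   pre_u = pre$u_coarse, pre_r_max_nm = pre$r_max_nm,
                   post_label = post$label, post_stage = post$stage,
                   post_u = post$u_coarse, post_r_max_nm = post$r_max_nm)
  })
  report <- dplyr::bind_rows(
    rows |> dplyr::count(.data$pre_stage) |>
      dplyr::rename(stage = "pre_stage") |>
      dplyr::mutate(side = "pre"),
    rows |> dplyr::count(.data$post_stage) |>
      dplyr::rename(stage = "post_stage") |>
      dplyr::mutate(side = "post")) |>
    dplyr::group_by(.data$side) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(typed = rows, report = report)
}

#' Axonal sorting: partner composition along the axon
#'
#' For each presynaptic cell, each synapse is assigned the path-length
#' distance from the soma node to the nearest skeleton node (on the
#' presynaptic skeleton), synapses are binned at `bin_width_um`, and the
#' excitatory/inhibitory ratio of postsynaptic partner labels is computed
#' per bin, ignoring uncertain labels. Across cells the per-bin mean and
#' standard error of the mean are reported (s.e.m. 0 with `n_cells` 1
#' when a single cell occupies a bin).
#'
#' @param typed Typed synapse tibble from [type_synapses()] (`$typed`).
#' @param skeletons Named list of presynaptic [skeleton()]s.
#' @param soma_nodes Named vector: segment id -> soma node id.
#' @param label_groups Named vector mapping postsynaptic labels to
#'   "excitatory" or "inhibitory"; unmapped labels are ignored.
#' @param bin_width_um Distance bin width (default 20).
#' @return List: `per_cell` (tibble: segment_id, bin, exc_ratio, n_syn),
#'   `summary` (tibble: bin, mean_exc_ratio, sem, n_cells).
#' @export
axonal_sorting <- function(typed, skeletons, soma_nodes, label_groups,
                           bin_width_um = 20) {
  per_cell <- list()
  for (seg in unique(typed$pre_segment_id)) {
    skel <- skeletons[[as.character(seg)]]
    soma <- soma_nodes[[as.character(seg)]]
    if (is.null(skel) || is.null(soma)) next
    d_soma <- skel_distances_from(skel, soma)
    if (length(d_soma) > 1 &&
          all(!is.finite(d_soma[names(d_soma) != as.character(soma)]))) {
      stop("soma node disconnected from skeleton of segment ", seg)
    }
    syn <- typed[typed$pre_segment_id == seg, ]
    grp <- unname(label_groups[syn$post_label])
    keep <- !is.na(grp)
    syn <- syn[keep, ]
    grp <- grp[keep]
    if (nrow(syn) == 0) next
    nd <- vapply(seq_len(nrow(syn)), function(i) {
      dx <- skel$nodes$x - syn$x[i]
      dy <- skel$nodes$y - syn$y[i]
      dz <- skel$nodes$z - syn$z[i]
      skel$nodes$node_id[which.min(dx^2 + dy^2 + dz^2)]
    }, numeric(1))
    dist_um <- unname(d_soma[as.character(nd)]) / 1000
    bin <- floor(dist_um / bin_width_um)
    tb <- tibble::tibble(bin = bin, exc = grp == "excitatory") |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(exc_ratio = mean(.data$exc),
                       n_syn = dplyr::n(), .groups = "drop")
    tb$segment_id <- seg
    per_cell[[length(per_cell) + 1]] <- tb
  }
  per_cell <- dplyr::bind_rows(per_cell)
  summary <- per_cell |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_exc_ratio = mean(.data$exc_ratio),
      sem = if (dplyr::n() > 1) sd(.data$exc_ratio) / sqrt(dplyr::n()) else 0,
      n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bin)
  list(per_cell = per_cell, summary = summary)
}
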