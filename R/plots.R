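# ggplot2 displays for the main result types.

#' @export
autoplot.segclr_checkpoint <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("nt_xent", "decorrelation",
                                            "total"),
                            names_to = "term", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss,
                                   color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss",
                  title = "Contrastive training trace") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.segclr_cv <- function(object, ...) {
  conf <- object$confusion |>
    dplyr::group_by(.data$truth) |>
    dplyr::mutate(fraction = .data$n / pmax(sum(.data$n), 1)) |>
    dplyr::ungroup()
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$estimate, y = .data$truth,
                                     fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$fraction)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Cell-level CV (mean F1 = %.3f)",
                                  object$mean_f1)) +
    ggplot2::theme_minimal()
}

#' Principal-component display of an embedding store
#'
#' Projects the 64-d embeddings onto their first two principal components
#' and colors points by an optional label table, a quick linear stand-in
#' for the non-linear manifold views used interactively.
#'
#' @param store Embedding store from [infer_embeddings()].
#' @param labels Optional tibble `segment_id`, `class_name`.
#' @return A ggplot object.
#' @export
plot_embedding_pca <- function(store, labels = NULL) {
  ec <- embedding_cols(store)
  pc <- stats::prcomp(as.matrix(store[, ec]), rank. = 2)
  df <- tibble::tibble(pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                       segment_id = store$segment_id)
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels, by = "segment_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                          color = .data$class_name))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2))
  }
  p + ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "PC1", y = "PC2", title = "Embedding space (PCA)") +
    ggplot2::theme_minimal()
}

#' Plot an axonal-sorting profile
#'
#' @param sorting Result of [axonal_sorting()].
#' @param bin_width_um Bin width used (for axis labeling).
#' @return A ggplot object.
#' @export
plot_axonal_sorting <- function(sorting, bin_width_um = 20) {
  df <- sorting$summary
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin + 0.5) * bin_width_um,
                                   y = .data$mean_exc_ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_exc_ratio - .data$sem,
      ymax = .data$mean_exc_ratio + .data$sem)) +
    ggplot2::labs(x = "path distance from soma (um)",
                  y = "excitatory fraction of partners",
                  title = "Axonal sorting profile") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
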