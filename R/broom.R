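# broom-style tidiers for fitted objects.

#' @export
tidy.segclr_cv <- function(x, ...) x$per_class

#' @export
glance.segclr_cv <- function(x, ...) {
  tibble::tibble(mean_f1 = x$mean_f1, n_repeats = x$n_repeats,
                 n_classes = length(x$classes))
}

#' @export
tidy.segclr_checkpoint <- function(x, ...) x$trace

#' @export
glance.segclr_checkpoint <- function(x, ...) {
  tibble::tibble(
    step = x$encoder$step,
    n_params = x$encoder$n_params,
    embedding_dim = x$encoder$config$embedding_dim,
    final_loss = if (nrow(x$trace)) x$trace$total[nrow(x$trace)] else NA_real_)
}

#' @export
glance.segclr_encoder <- function(x, ...) {
  tibble::tibble(view_size = x$config$view_size,
                 embedding_dim = x$config$embedding_dim,
                 projection_dim = x$config$projection_dim,
                 n_params = x$n_params, step = x$step)
}

#' @export
tidy.segclr_sngp <- function(x, ...) {
  tibble::tibble(class = x$classes)
}

#' @export
glance.segclr_sngp <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), width = x$width,
                 n_rff = x$n_rff)
}
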