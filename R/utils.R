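#' Confusion matrix as a tibble
#'
#' Cross-tabulates true against predicted class labels over a fixed class
#' set, including classes never predicted (zero rows/columns are kept).
#'
#' @param truth Character vector of true labels.
#' @param estimate Character vector of predicted labels, same length.
#' @param classes Class levels; defaults to the union of both vectors.
#' @return A tibble with columns `truth`, `estimate`, `n`.
#' @export
confusion_tibble <- function(truth, estimate, classes = NULL) {
  stopifnot(length(truth) == length(estimate))
  classes <- classes %||% sort(union(unique(truth), unique(estimate)))
  tab <- table(factor(truth, levels = classes),
               factor(estimate, levels = classes))
  out <- tibble::as_tibble(tab, .name_repair = "minimal")
  names(out) <- c("truth", "estimate", "n")
  out
}

#' Per-class and macro-averaged F1 scores
#'
#' F1 is the harmonic mean of precision and recall per class; a class with
#' no true and no predicted examples contributes F1 = NA and is dropped from
#' the macro mean, while a class present in the data but never correctly
#' matched scores 0.
#'
#' @inheritParams confusion_tibble
#' @return A list with `per_class` (tibble: class, precision, recall, f1)
#'   and `macro_f1` (unweighted mean over classes).
#' @export
f1_scores <- function(truth, estimate, classes = NULL) {
  classes <- classes %||% sort(union(unique(truth), unique(estimate)))
  per <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    if (tp + fp + fn == 0L) {
      return(tibble::tibble(class = cl, precision = NA_real_,
                            recall = NA_real_, f1 = NA_real_))
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1)
  })
  list(per_class = per, macro_f1 = mean(per$f1, na.rm = TRUE))
}

#' Macro-averaged F1
#'
#' Convenience wrapper around [f1_scores()].
#' @inheritParams confusion_tibble
#' @return Unweighted mean F1 over classes.
#' @export
macro_f1 <- function(truth, estimate, classes = NULL) {
  f1_scores(truth, estimate, classes)$macro_f1
}

# Area under the ROC curve by the rank-sum (Mann-Whitney) identity.
# `scores` higher for positives; ties handled by midranks.
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative examples")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic integer sub-seed derived from a base seed and a tag,
# kept under 2^31 for R's 32-bit integers.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

# Stable softmax over rows of a matrix.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}
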