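#' Normalized temperature-scaled cross-entropy (NT-Xent) contrastive loss
#'
#' Rows of `projections` are arranged as N positive pairs interleaved:
#' rows (1,2), (3,4), ... are partners. Each row is L2-normalized; for
#' example i with partner j the per-example loss is
#' `-log( exp(sim(i,j)/tau) / sum_{k != i} exp(sim(i,k)/tau) )`
#' with cosine similarity, i.e. every other example in the batch (2N - 2
#' of them, drawn from other segments) acts as a negative. The returned
#' value is the mean over all 2N examples.
#'
#' @param projections Numeric matrix with 2N rows (N >= 2) of projection
#'   vectors; rows must be nonzero.
#' @param tau Temperature (> 0), default 0.1.
#' @return Scalar loss (>= 0).
#' @export
nt_xent_loss <- function(projections, tau = 0.1) {
  nt_xent_with_grad(projections, tau)$loss
}

# Loss plus gradient with respect to the (unnormalized) projections.
nt_xent_with_grad <- function(projections, tau = 0.1) {
  P <- as.matrix(projections)
  stopifnot(tau > 0, nrow(P) %% 2 == 0, nrow(P) >= 4)
  nrm <- sqrt(rowSums(P^2))
  if (any(nrm < 1e-12)) stop("zero-norm projection row")
  Z <- P / nrm
  n <- nrow(Z)
  partner <- as.integer(seq_len(n) + c(1, -1))  # 2,1,4,3,...
  S <- (Z %*% t(Z)) / tau
  diag(S) <- -Inf                               # k != i
  m <- apply(S, 1, max)
  E <- exp(S - m)
  denom <- rowSums(E)
  A <- E / denom                                # row-softmax over k != i
  pos <- S[cbind(seq_len(n), partner)]
  loss <- mean(-(pos - m) + log(denom))
  G <- A
  G[cbind(seq_len(n), partner)] <- G[cbind(seq_len(n), partner)] - 1
  G <- G / n
  G[!is.finite(G)] <- 0
  dZ <- ((G + t(G)) %*% Z) / tau
  # back through row normalization z = p / ||p||
  dP <- (dZ - Z * rowSums(Z * dZ)) / nrm
  list(loss = loss, grad = dP)
}

#' Decorrelation loss over embedding dimensions
#'
#' The mean squared off-diagonal entry of the Pearson correlation matrix
#' `C` between embedding dimensions over the batch:
#' `L = (1 / (d^2 - d)) * sum_{i} sum_{j != i} C_ij^2`.
#' Added to the contrastive objective it discourages redundant embedding
#' dimensions. Dimensions with zero variance over the batch have their
#' correlations defined as 0.
#'
#' @param embeddings Numeric matrix, rows = batch examples, columns = d
#'   embedding dimensions (d >= 2, batch >= 2).
#' @return Scalar loss in `[0, 1]`.
#' @export
decorrelation_loss <- function(embeddings) {
  decorrelation_with_grad(embeddings)$loss
}

decorrelation_with_grad <- function(embeddings) {
  X <- as.matrix(embeddings)
  n <- nrow(X); d <- ncol(X)
  if (d < 2) stop("need at least 2 embedding dimensions")
  stopifnot(n >= 2)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sdv <- sqrt(colSums(Xc^2) / (n - 1))
  live <- sdv > 1e-12
  A <- Xc
  A[, live] <- sweep(Xc[, live, drop = FALSE], 2, sdv[live], "/")
  A[, !live] <- 0
  C <- crossprod(A) / (n - 1)
  off <- C; diag(off) <- 0
  s <- 1 / (d^2 - d)
  loss <- s * sum(off^2)
  G <- 2 * s * off                       # dL/dC, zero diagonal
  dA <- A %*% (G + t(G)) / (n - 1)
  dXc <- dA
  if (any(live)) {
    Al <- A[, live, drop = FALSE]
    dAl <- dA[, live, drop = FALSE]
    dsd <- -colSums(dAl * Al) / sdv[live]
    dXc[, live] <- sweep(dAl, 2, sdv[live], "/") +
      sweep(Al, 2, dsd / (n - 1), "*")
  }
  dXc[, !live] <- 0
  dX <- sweep(dXc, 2, colMeans(dXc))
  list(loss = loss, grad = dX, C = C)
}
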