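#' Exact t-SNE projection
#'
#' A compact exact (non-Barnes-Hut) implementation of t-distributed
#' stochastic neighbour embedding, intended for the small point sets used
#' in embedding diagnostics (hundreds to a few thousand points). Gaussian
#' input similarities are calibrated per point by binary search on the
#' bandwidth to match the target perplexity; the low-dimensional map uses
#' the Student-t kernel and is optimised by gradient descent with momentum
#' and early exaggeration.
#'
#' @param X Numeric matrix (rows = points).
#' @param dims Output dimensionality (default 2).
#' @param perplexity Target perplexity; internally capped at (n-1)/3.
#' @param n_iter Gradient iterations (default 400).
#' @param seed Integer seed for the random initial map.
#' @return An n x `dims` coordinate matrix.
#' @export
tsne_project <- function(X, dims = 2L, perplexity = 15, n_iter = 400L,
                         seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2L)
  perplexity <- max(1, min(perplexity, (n - 1) / 3))

  # squared Euclidean distances
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(X), 0)
  diag(D2) <- Inf

  # per-point bandwidth calibration to the target entropy
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp <= 0) { p <- as.numeric(di == min(di)); sp <- sum(p) }
      p <- p / sp
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- with_seed(seed, matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  dY <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  momentum <- 0.5
  eta <- min(100, max(2, n)) # small point sets need gentler steps
  exag <- 4; exag_until <- min(100L, n_iter %/% 4L)
  Pe <- P * exag
  for (it in seq_len(n_iter)) {
    if (it == exag_until + 1L) Pe <- P
    if (it == 21L) momentum <- 0.8
    ssy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(ssy, ssy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    # clip per-point displacement so degenerate inputs cannot diverge
    step <- sqrt(rowSums(dY^2))
    big <- step > 5
    if (any(big)) dY[big, ] <- dY[big, , drop = FALSE] * (5 / step[big])
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
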