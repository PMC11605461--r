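#' 2-D t-SNE layout of pathway embeddings
#'
#' Exact (non-approximated) t-SNE: Gaussian input affinities calibrated
#' per point to the target perplexity by bisection, Student-t similarities
#' in the plane, gradient descent with momentum and early exaggeration,
#' PCA initialisation scaled small. Suitable for the cohort sizes this
#' package plots (up to a few thousand pathways). The layout is for
#' plotting only; clustering always operates on the high-dimensional
#' embeddings.
#'
#' @param embeddings `n x H` numeric matrix (n >= 10).
#' @param seed integer seed (layout is deterministic given the seed).
#' @param perplexity effective neighbour count (default 30; reduced
#'   automatically when n is small).
#' @param n_iter gradient-descent iterations.
#' @return `n x 2` coordinate matrix.
#' @export
embed2d <- function(embeddings, seed = 1L, perplexity = 30,
                    n_iter = 400L) {
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 embeddings")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  set.seed(seed)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { h <- 0; pn <- p } else {
        pn <- p / sp
        h <- -sum(pn[pn > 0] * log(pn[pn > 0]))
      }
      if (abs(h - logU) < 1e-5) break
      if (h > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- pn
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # PCA init, small scale
  Y <- stats::prcomp(X, rank. = 2L)$x[, 1:2, drop = FALSE]
  Y <- Y / stats::sd(Y[, 1L]) * 1e-4
  Y <- Y + matrix(stats::rnorm(2L * n, 0, 1e-5), n, 2L)
  vel <- matrix(0, n, 2L)
  eta <- 200; momentum <- 0.5
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100L) 12 else 1
    mom <- if (it <= 250L) 0.5 else 0.8
    d2y <- as.matrix(stats::dist(Y))^2
    Wq <- 1 / (1 + d2y); diag(Wq) <- 0
    Q <- pmax(Wq / sum(Wq), 1e-12)
    M <- (ex * P - Q) * Wq
    grad <- 4 * (diag(rowSums(M)) - M) %*% Y
    vel <- mom * vel - eta * grad
    Y <- Y + vel
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  dimnames(Y) <- list(rownames(embeddings), c("tsne1", "tsne2"))
  Y
}
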