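#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and returns
#' the top-k coordinates scaled by the square roots of the (positive)
#' eigenvalues. Percent variance is computed over positive eigenvalues only.
#' Axis signs are fixed deterministically: each axis is flipped so its
#' largest-magnitude coordinate is positive (classical scaling is defined only
#' up to sign).
#'
#' @param D symmetric dissimilarity matrix.
#' @param k embedding dimension (`k <= n - 1`); shrunk with a warning if fewer
#'   positive eigenvalues exist.
#' @return list of class `buds_embedding`: `coords` (n x k), `eigenvalues`,
#'   `pct_variance`, `method_tag = "pcoa"`.
#' @export
pcoa <- function(D, k = 2) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (k > n - 1) stop("k must be at most n - 1")
  cs <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  pos <- which(cs$eig > 1e-9 * max(abs(cs$eig)))
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalues; shrinking k")
    k <- length(pos)
  }
  coords <- cs$points[, seq_len(k), drop = FALSE]
  for (a in seq_len(k)) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(D)
  ev <- cs$eig[seq_len(k)]
  structure(list(coords = coords, eigenvalues = ev,
                 pct_variance = 100 * ev / sum(cs$eig[pos]),
                 method_tag = "pcoa"),
            class = "buds_embedding")
}

#' @export
print.buds_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: %d samples in %d dimensions",
              x$method_tag, nrow(x$coords), ncol(x$coords)))
  if (!is.null(x$pct_variance))
    cat(sprintf(" (%% variance: %s)",
                paste(sprintf("%.1f", x$pct_variance), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' t-SNE embedding of a dissimilarity matrix
#'
#' Exact (non-approximate) t-distributed stochastic neighbor embedding run in
#' precomputed-distance mode: input similarities from a per-point Gaussian
#' kernel calibrated to `perplexity` by bisection, Student-t low-dimensional
#' kernel, gradient descent with momentum and early exaggeration.
#' Reproducible per seed. Intended for the moderate n this package targets.
#'
#' @param D symmetric dissimilarity matrix.
#' @param k embedding dimension (2 or 3).
#' @param seed integer seed.
#' @param perplexity effective neighborhood size; must satisfy
#'   `perplexity < (n - 1) / 3`.
#' @param max_iter gradient-descent iterations.
#' @return `buds_embedding` with `method_tag = "tsne"`.
#' @export
tsne_embed <- function(D, k = 2, seed = 1, perplexity = 10, max_iter = 500) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity must be below (n - 1) / 3")
  if (perplexity < 1) stop("perplexity must be at least 1")
  set.seed(as.integer(seed))
  D2 <- D^2
  ## per-row precision calibration to match log-perplexity
  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-10; hi <- 1e10; beta <- 1
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- w / sw
      H <- -sum(ifelse(p > 0, p * log(p), 0))
      if (abs(H - target) < 1e-6) break
      if (H > target) lo <- beta else hi <- beta
      beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * k, sd = 1e-4), n, k)
  G <- matrix(0, n, k); gains <- matrix(1, n, k)
  for (it in seq_len(max_iter)) {
    ex <- if (it <= 100) 4 else 1
    mom <- if (it <= 250) 0.5 else 0.8
    sqY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sqY, sqY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    dir <- sign(grad)
    gains <- ifelse(dir != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - 100 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(D)
  structure(list(coords = Y, eigenvalues = NULL, pct_variance = NULL,
                 method_tag = "tsne", perplexity = perplexity, seed = seed),
            class = "buds_embedding")
}

#' Posterior trajectory paths through an embedding
#'
#' For each of `n_paths` posterior draws, the ordering of samples by ascending
#' \eqn{\tau} in that draw (a path to superimpose on a 2D/3D embedding; 50
#' paths give a visual sense of ordering uncertainty). Also returns one
#' mode-path: the samples whose \eqn{\hat\tau} are nearest to `n_highlight`
#' evenly spaced grid points on `[0, 1]`, connected in grid order.
#'
#' @param fit a [buds()] fit.
#' @param n_paths number of posterior paths (default 50; shrunk with a
#'   warning if more than the stored draws).
#' @param n_highlight size of the evenly spaced grid for the mode-path.
#' @return list of class `buds_paths`: `paths` (list of index permutations),
#'   `mode_path` (index vector, deduplicated, in grid order).
#' @export
trajectory_paths <- function(fit, n_paths = 50, n_highlight = 10) {
  stopifnot(inherits(fit, "buds"))
  if (n_paths > fit$draws) {
    warning("n_paths exceeds stored draws; using ", fit$draws)
    n_paths <- fit$draws
  }
  idx <- seq_len(n_paths)
  paths <- lapply(idx, function(t)
    order(fit$tau_draws[t, ], seq_len(fit$n)))
  grid <- seq(0, 1, length.out = n_highlight)
  sel <- vapply(grid, function(g) which.min(abs(fit$tau_hat - g)), 1L)
  mode_path <- sel[!duplicated(sel)]
  structure(list(paths = paths, mode_path = mode_path,
                 n_highlight = n_highlight),
            class = "buds_paths")
}
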