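#' K-nearest-neighbor variance scales for dissimilarities
#'
#' Estimates a relative noise variance for each dissimilarity \eqn{d_{ij}}
#' from local information: the empirical (unbiased) variance of the set
#' \deqn{D^K_{ij} = \{ d(x_i, x_k) : x_k \in \Gamma_K(x_j) \setminus \{x_i\} \}
#'   \cup \{ d(x_j, x_l) : x_l \in \Gamma_K(x_i) \setminus \{x_j\} \},}
#' i.e. distances from each endpoint to the K nearest neighbors of the other
#' endpoint, excluding the endpoints themselves so that no self-distance of 0
#' inflates the estimate. The raw variances are only meaningful relatively, so
#' they are normalized by their off-diagonal mean; the absolute noise level
#' \eqn{\sigma_\epsilon} is a model parameter estimated jointly with the
#' latent coordinates. Pairs in densely sampled regions receive small scales,
#' pairs involving isolated points large ones.
#'
#' Raw variances are floored at `1e-6 * mean(d)^2` before normalization so
#' degenerate (equidistant or duplicated) configurations keep strictly
#' positive scales. Ties at the K-th neighbor are broken by sample index.
#'
#' @param D symmetric dissimilarity matrix, n >= 4.
#' @param K neighborhood size, `2 <= K <= n - 2`. Small values (the package
#'   default in [buds()] is 10) capture local density differences.
#' @return an object of class `buds_scales`: list with `values` (n x n matrix
#'   of normalized scales \eqn{s^2_{ij}}, off-diagonal mean exactly 1),
#'   `raw_variances`, and `K`.
#' @export
#' @examples
#' D <- as.matrix(dist(seq(0, 1, length.out = 8)))
#' S <- knn_variance_scales(D, K = 3)
#' mean(S$values[upper.tri(S$values)])  # 1 by construction
knn_variance_scales <- function(D, K) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  K <- as.integer(K)
  if (K < 2L || K > n - 2L)
    stop("K must satisfy 2 <= K <= n - 2 (n = ", n, ")")
  ## neighbor lists: K nearest by dissimilarity, ties broken by sample index
  ## (order() is stable on the running index tie-breaker)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    nb[[i]] <- ord[seq_len(K)]
  }
  raw <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ks <- setdiff(nb[[j]], i)   # neighbors of x_j, x_i excluded
      ls <- setdiff(nb[[i]], j)   # neighbors of x_i, x_j excluded
      dset <- c(D[i, ks], D[j, ls])
      if (length(dset) < 2L)
        stop("fewer than 2 distances available for pair (", i, ",", j, ")")
      raw[i, j] <- raw[j, i] <- stats::var(dset)
    }
  }
  up <- upper.tri(raw)
  floor_val <- 1e-6 * mean(D[up])^2
  raw_fl <- pmax(raw, floor_val)
  s2 <- raw_fl / mean(raw_fl[up])
  diag(s2) <- 0
  dimnames(s2) <- dimnames(raw) <- dimnames(D)
  structure(list(values = s2, raw_variances = raw, K = K),
            class = "buds_scales")
}

#' @export
print.buds_scales <- function(x, ...) {
  up <- upper.tri(x$values)
  cat(sprintf(
    "KNN variance scales (K = %d, n = %d): s2 range [%.3g, %.3g], mean 1\n",
    x$K, nrow(x$values), min(x$values[up]), max(x$values[up])))
  invisible(x)
}

## Coerce user input (buds_scales | matrix | NULL) to an s2 matrix
as_scales_matrix <- function(S, D, K = 10L) {
  if (is.null(S)) {
    n <- nrow(D)
    K <- min(K, n - 2L)
    return(knn_variance_scales(D, K = K)$values)
  }
  if (inherits(S, "buds_scales")) S <- S$values
  S <- as.matrix(S)
  if (!all(dim(S) == dim(D))) stop("scales not conformable with 'D'")
  up <- upper.tri(S)
  if (any(S[up] <= 0)) stop("noise scales must be strictly positive")
  if (abs(mean(S[up]) - 1) > 1e-6)
    warning("noise scales are not mean-normalized; normalizing")
  S / mean(S[up])
}

#' Uniform (homoscedastic) noise scales
#'
#' Convenience constructor giving every pair the same relative variance
#' (all scales 1), for fitting without the KNN heteroscedasticity estimate.
#'
#' @param n number of samples or a dissimilarity matrix to take n (and ids) from.
#' @return `buds_scales` object with all off-diagonal scales 1.
#' @export
uniform_scales <- function(n) {
  if (is.matrix(n)) {
    ids <- rownames(n); n <- nrow(n)
  } else ids <- paste0("s", seq_len(n))
  v <- matrix(1, n, n); diag(v) <- 0
  dimnames(v) <- list(ids, ids)
  structure(list(values = v, raw_variances = v, K = NA_integer_),
            class = "buds_scales")
}
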