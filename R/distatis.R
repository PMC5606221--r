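#' Posterior dissimilarity cube
#'
#' For `t` posterior draws, forms that draw's latent distance matrix
#' \eqn{\Delta^* = b^* + \rho^* |\tau_i^* - \tau_j^*|} and emits a noisy copy
#' \eqn{D^*} with independent upper-triangle Gamma entries of mean
#' \eqn{\delta^*_{ij}} and variance \eqn{s^2_{ij}\sigma_\epsilon^{*2}},
#' symmetrized — i.e. replays the generative model forward from the posterior.
#' The cube is the input to [distatis()].
#'
#' @param fit a [buds()] fit.
#' @param t number of slices (`<= fit$draws`), default 50.
#' @param seed integer seed for the Gamma noise.
#' @return array of class `buds_cube`, n x n x t, with attributes `draw_ids`
#'   and `seed`.
#' @export
dissimilarity_cube <- function(fit, t = 50, seed = 1) {
  stopifnot(inherits(fit, "buds"))
  if (t > fit$draws) stop("t must be at most the number of stored draws")
  set.seed(as.integer(seed))
  n <- fit$n
  up <- which(upper.tri(matrix(0, n, n)))
  s2 <- fit$S[up]
  cube <- array(0, dim = c(n, n, t),
                dimnames = list(rownames(fit$D), rownames(fit$D), NULL))
  for (s in seq_len(t)) {
    tau <- fit$tau_draws[s, ]
    delta <- mean_dissimilarity_matrix(tau, fit$scalar_draws$b[s],
                                       fit$scalar_draws$rho[s],
                                       fit$hyper)
    sr <- gamma_shape_rate(delta[up], s2 * fit$scalar_draws$sigma_eps[s]^2)
    sl <- matrix(0, n, n)
    sl[up] <- pmax(stats::rgamma(length(up), sr$shape, sr$rate), 1e-12)
    cube[, , s] <- sl + t(sl)
  }
  structure(cube, draw_ids = seq_len(t), seed = as.integer(seed),
            class = c("buds_cube", "array"))
}

mean_dissimilarity_matrix <- function(tau, b, rho, hyper) {
  delta <- as.matrix(stats::dist(tau))
  if (hyper$use_shift_scale) delta <- b + rho * delta
  delta <- pmax(delta, hyper$mu_floor)
  diag(delta) <- 0
  delta
}

#' Simulate posterior dissimilarity matrices from a BUDS fit
#'
#' `simulate()` method wrapping [dissimilarity_cube()]: each simulation is one
#' posterior-predictive dissimilarity matrix.
#'
#' @param object a `buds` fit.
#' @param nsim number of matrices (cube slices).
#' @param seed integer seed.
#' @param ... unused.
#' @return a `buds_cube` array (n x n x nsim).
#' @export
simulate.buds <- function(object, nsim = 50, seed = 1, ...) {
  dissimilarity_cube(object, t = nsim, seed = seed)
}

## double-centered cross-product of a squared-dissimilarity matrix
cross_product <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% D^2 %*% J
}

#' DiSTATIS registration of a dissimilarity cube
#'
#' Three-way metric multidimensional scaling: each slice is turned into a
#' double-centered cross-product matrix normalized by its leading eigenvalue;
#' slices are weighted by the leading eigenvector of their RV-coefficient
#' similarity matrix \eqn{C_{ab} = tr(S_a S_b) / \sqrt{tr(S_a^2) tr(S_b^2)}}
#' (weights `alpha` nonnegative, summing to 1); the compromise
#' \eqn{S_+ = \sum_s \alpha_s S_s} is eigendecomposed into consensus
#' coordinates \eqn{V \Lambda^{1/2}}, and each slice is projected into the
#' compromise space as \eqn{F_s = S_s V \Lambda^{-1/2}}.
#'
#' @param cube `buds_cube` or n x n x t array of dissimilarity matrices over
#'   the same samples, `t >= 2`.
#' @param k dimension of the consensus space (default 2).
#' @return list of class `buds_distatis`: `consensus` (n x k),
#'   `slice_projections` (t x n x k), `alpha` (t), `eigenvalues` (of the
#'   compromise), `normalization = "leading-eigenvalue"`.
#' @export
distatis <- function(cube, k = 2) {
  dims <- dim(cube)
  if (length(dims) != 3L || dims[1] != dims[2])
    stop("'cube' must be an n x n x t array")
  t <- dims[3]
  if (t < 2) stop("need at least 2 slices")
  n <- dims[1]
  Ss <- vector("list", t)
  keep <- logical(t)
  for (s in seq_len(t)) {
    S <- cross_product(cube[, , s])
    S <- (S + t(S)) / 2
    lam1 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values[1]
    if (lam1 <= 1e-12) {
      warning("slice ", s, " has zero leading eigenvalue; dropped")
      keep[s] <- FALSE
    } else {
      Ss[[s]] <- S / lam1
      keep[s] <- TRUE
    }
  }
  Ss <- Ss[keep]
  t <- length(Ss)
  if (t < 2) stop("fewer than 2 usable slices")
  ## RV-coefficient similarity between slices
  C <- matrix(0, t, t)
  tr2 <- vapply(Ss, function(S) sum(S * S), 0)
  for (a in seq_len(t)) for (b2 in a:t) {
    C[a, b2] <- C[b2, a] <- sum(Ss[[a]] * Ss[[b2]]) / sqrt(tr2[a] * tr2[b2])
  }
  ec <- eigen(C, symmetric = TRUE)
  alpha <- ec$vectors[, 1]
  if (sum(alpha) < 0) alpha <- -alpha
  alpha <- pmax(alpha, 0)
  alpha <- alpha / sum(alpha)
  Splus <- Reduce(`+`, Map(`*`, Ss, alpha))
  es <- eigen(Splus, symmetric = TRUE)
  pos <- which(es$values > 1e-12)
  if (length(pos) < k) {
    warning("compromise has only ", length(pos),
            " positive eigenvalues; shrinking k")
    k <- length(pos)
  }
  V <- es$vectors[, seq_len(k), drop = FALSE]
  lam <- es$values[seq_len(k)]
  consensus <- V %*% diag(sqrt(lam), k)
  for (a in seq_len(k)) {   # deterministic axis signs
    i <- which.max(abs(consensus[, a]))
    if (consensus[i, a] < 0) {
      consensus[, a] <- -consensus[, a]
      V[, a] <- -V[, a]
    }
  }
  rownames(consensus) <- dimnames(cube)[[1]]
  proj <- array(0, dim = c(t, n, k))
  Vl <- V %*% diag(1 / sqrt(lam), k)
  for (s in seq_len(t)) proj[s, , ] <- Ss[[s]] %*% Vl
  structure(list(consensus = consensus, slice_projections = proj,
                 alpha = alpha, eigenvalues = es$values,
                 normalization = "leading-eigenvalue"),
            class = "buds_distatis")
}

#' @export
print.buds_distatis <- function(x, ...) {
  cat(sprintf(
    "DiSTATIS compromise: %d samples, %d slices, %d axes (lambda1 = %.3f)\n",
    nrow(x$consensus), length(x$alpha), ncol(x$consensus),
    x$eigenvalues[1]))
  invisible(x)
}
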