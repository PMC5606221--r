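#' Generate a gradient-structured synthetic data matrix
#'
#' Produces a features x samples matrix whose samples lie along a planted
#' one-dimensional gradient with known coordinates `tau_true`, emulating the
#' kinds of data the latent-ordering model targets:
#' \describe{
#'   \item{`counts`}{each feature k has a unimodal (Gaussian-bump) response
#'     \eqn{\mu_k(\tau) = h \exp(-(\tau - c_k)^2 / 2w^2)} with centers
#'     \eqn{c_k} equally spaced on `[0, 1]`; entries are Poisson draws —
#'     species turning over along an environmental gradient, yielding the
#'     banded/triangular presence structure that seriation should recover.}
#'   \item{`continuous`}{smooth monotone sigmoid feature curves (half rising,
#'     half falling, staggered midpoints) plus Gaussian noise — expression
#'     kinetics along developmental time.}
#'   \item{`binary`}{thresholded logistic gradient responses — vote-type
#'     data with a latent left-right spectrum.}
#' }
#' Sampling density along the gradient follows `tau ~ Beta(a, b)`; skewed
#' choices (e.g. `a = 3, b = 1`) emulate unevenly collected datasets.
#'
#' @param n samples (>= 10), `p` features (>= 20).
#' @param p number of features.
#' @param mode `"counts"`, `"continuous"` or `"binary"`.
#' @param a,b Beta parameters of the sampling density of `tau_true`.
#' @param h peak expected count for `counts` mode.
#' @param width response width `w` of the unimodal curves (default 0.15, so a
#'   feature spans roughly a third of the gradient).
#' @param noise_sd Gaussian noise standard deviation (`continuous` mode).
#' @param seed integer seed; output is reproducible from the arguments.
#' @return list of class `buds_sim`: `X` (a [data_matrix()]), `tau_true`,
#'   and `generator_params`.
#' @export
#' @examples
#' sim <- generate_gradient(n = 30, p = 60, mode = "counts", seed = 1)
#' dim(sim$X)
generate_gradient <- function(n = 50, p = 200,
                              mode = c("counts", "continuous", "binary"),
                              a = 1, b = 1, h = 25, width = 0.15,
                              noise_sd = 0.1, seed = 1) {
  mode <- match.arg(mode)
  if (n < 10) stop("need n >= 10")
  if (p < 20) stop("need p >= 20")
  set.seed(as.integer(seed))
  tau <- stats::rbeta(n, a, b)
  centers <- seq(0, 1, length.out = p)
  X <- switch(mode,
    counts = {
      g <- exp(-outer(centers, tau, function(c, t) (t - c)^2) /
                 (2 * width^2))
      ## per-feature peak heights h_k equalize the expected total abundance
      ## across features; otherwise features near the gradient ends carry
      ## less mass and the planted banded structure is distorted
      h_k <- h * mean(rowSums(g)) / pmax(rowSums(g), 1e-8)
      mu <- g * h_k
      matrix(stats::rpois(p * n, mu), p, n)
    },
    continuous = {
      sign_k <- rep(c(1, -1), length.out = p)
      mid <- centers
      f <- stats::plogis(outer(mid, tau, function(m, t) (t - m) / width))
      f <- sweep(f, 1, sign_k, function(x, s) ifelse(s > 0, x, 1 - x))
      f + matrix(stats::rnorm(p * n, sd = noise_sd), p, n)
    },
    binary = {
      pr <- stats::plogis(outer(centers, tau,
                                function(m, t) (t - m) / (width / 2)))
      matrix(stats::rbinom(p * n, 1, pr), p, n)
    })
  ids <- sprintf("s%02d", seq_len(n))
  X <- data_matrix(X, kind = if (mode == "continuous") "continuous"
                             else if (mode == "binary") "binary" else "counts",
                   feature_ids = sprintf("f%03d", seq_len(p)),
                   sample_ids = ids)
  structure(list(X = X, tau_true = stats::setNames(tau, ids),
                 generator_params = list(n = n, p = p, mode = mode, a = a,
                                         b = b, h = h, width = width,
                                         noise_sd = noise_sd, seed = seed)),
            class = "buds_sim")
}

#' Draw a dissimilarity matrix from the generative model itself
#'
#' The exact-model fixture for parameter recovery: draws
#' `tau_true ~ Beta(a, b)`, forms \eqn{\tilde\delta_{ij} = b + \rho |\tau_i -
#' \tau_j|}, and emits a symmetric matrix with independent upper-triangle
#' Gamma entries with mean \eqn{\tilde\delta_{ij}} and variance
#' \eqn{s^2_{ij}\sigma_\epsilon^2}.
#'
#' @param n number of samples.
#' @param b shift (>= 0).
#' @param rho slope (> 0).
#' @param sigma_eps noise level (> 0).
#' @param scale_pattern `"uniform"` (all \eqn{s^2_{ij} = 1}) or
#'   `"dense-middle"` (scales increasing toward the gradient ends,
#'   mean-normalized).
#' @param a,b_beta Beta parameters of the `tau_true` sampling density.
#' @param seed integer seed.
#' @return list of class `buds_sim_draw`: `D`, `tau_true`, `params_true`,
#'   `S` (the scales used).
#' @export
generate_model_draw <- function(n = 50, b = 0.05, rho = 1, sigma_eps = 0.3,
                                scale_pattern = c("uniform", "dense-middle"),
                                a = 1, b_beta = 1, seed = 1) {
  scale_pattern <- match.arg(scale_pattern)
  if (sigma_eps <= 0 || rho <= 0 || b < 0) stop("invalid generator parameters")
  set.seed(as.integer(seed))
  tau <- stats::rbeta(n, a, b_beta)
  for (tries in 1:100) {
    if (b > 0 || min(stats::dist(tau)) > 0) break
    warning("tied tau with b = 0; re-drawing with jitter")
    tau <- pmin(pmax(tau + stats::rnorm(n, sd = 1e-4), 0), 1)
  }
  ids <- sprintf("s%02d", seq_len(n))
  delta <- b + rho * as.matrix(stats::dist(tau))
  diag(delta) <- 0
  s2 <- matrix(1, n, n)
  if (scale_pattern == "dense-middle") {
    w <- 0.5 + 2 * abs(tau - 0.5)          # larger noise near the ends
    s2 <- outer(w, w)
    s2 <- s2 / mean(s2[upper.tri(s2)])
  }
  D <- matrix(0, n, n)
  up <- which(upper.tri(D))
  sr <- gamma_shape_rate(delta[up], s2[up] * sigma_eps^2)
  ## Gamma support is open at 0: guard against floating-point underflow to 0
  D[up] <- pmax(stats::rgamma(length(up), shape = sr$shape, rate = sr$rate),
                1e-12)
  D <- D + t(D)
  dimnames(D) <- dimnames(s2) <- list(ids, ids)
  diag(s2) <- 0
  structure(list(
    D = check_dissimilarity(D), tau_true = stats::setNames(tau, ids),
    S = s2,
    params_true = list(b = b, rho = rho, sigma_eps = sigma_eps,
                       scale_pattern = scale_pattern, a = a, b_beta = b_beta,
                       seed = seed)),
    class = "buds_sim_draw")
}
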