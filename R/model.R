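#' Hyperparameters of the BUDS model
#'
#' Scale parameters of the half-Cauchy hyperpriors and structural switches.
#' All half-Cauchy scales default to 2.5, a standard weakly informative choice
#' for positive scale parameters. `use_shift_scale` switches the mean of the
#' Gamma likelihood between the shift/scale transform
#' \eqn{\tilde\delta_{ij} = b + \rho |\tau_i - \tau_j|} (default) and the plain
#' latent distance \eqn{|\tau_i - \tau_j|}. `mu_floor` keeps the Gamma mean
#' strictly positive when latent coordinates tie.
#'
#' @param gamma_tau half-Cauchy scale for the Beta concentration parameters
#'   \eqn{\alpha_\tau, \beta_\tau} (centered at 1).
#' @param gamma_eps half-Cauchy scale for the noise level \eqn{\sigma_\epsilon}
#'   (centered at 0).
#' @param gamma_b half-Cauchy scale for the shift \eqn{b} (centered at 0).
#' @param gamma_rho half-Cauchy scale for the slope \eqn{\rho} (centered at 1).
#' @param use_shift_scale logical, see above.
#' @param mu_floor small positive floor for the Gamma mean.
#' @return list of class `buds_hyper`.
#' @export
buds_hyperparams <- function(gamma_tau = 2.5, gamma_eps = 2.5,
                             gamma_b = 2.5, gamma_rho = 2.5,
                             use_shift_scale = TRUE, mu_floor = 1e-6) {
  stopifnot(gamma_tau > 0, gamma_eps > 0, gamma_b > 0, gamma_rho > 0,
            mu_floor > 0)
  structure(list(gamma_tau = gamma_tau, gamma_eps = gamma_eps,
                 gamma_b = gamma_b, gamma_rho = gamma_rho,
                 use_shift_scale = isTRUE(use_shift_scale),
                 mu_floor = mu_floor),
            class = "buds_hyper")
}

#' Convert a Gamma mean/variance to shape/rate
#'
#' \eqn{\alpha = \mu^2/\sigma^2}, \eqn{\beta = \mu/\sigma^2}, so that
#' \eqn{\alpha/\beta = \mu} and \eqn{\alpha/\beta^2 = \sigma^2} exactly.
#' Vectorized.
#'
#' @param mu positive mean(s).
#' @param var positive variance(s).
#' @return list with components `shape` and `rate`.
#' @export
#' @examples
#' gamma_shape_rate(2, 4)  # shape 1, rate 0.5
gamma_shape_rate <- function(mu, var) {
  if (any(mu <= 0) || any(var <= 0))
    stop("'mu' and 'var' must be strictly positive")
  list(shape = mu^2 / var, rate = mu / var)
}

#' Model-expected dissimilarity between two samples
#'
#' The Gamma mean for pair (i, j): `max(mu_floor, b + rho * |tau_i - tau_j|)`
#' under the shift/scale transform, `max(mu_floor, |tau_i - tau_j|)` without.
#'
#' @param params list with at least `tau`, `b`, `rho` (see [buds_params()]).
#' @param i,j distinct sample indices.
#' @param hyper [buds_hyperparams()].
#' @return positive scalar.
#' @export
expected_dissimilarity <- function(params, i, j, hyper = buds_hyperparams()) {
  if (i == j) stop("i and j must be distinct")
  d <- abs(params$tau[i] - params$tau[j])
  m <- if (hyper$use_shift_scale) params$b + params$rho * d else d
  max(hyper$mu_floor, m)
}

#' Bundle one realization of all latent parameters
#'
#' @param tau numeric vector in `[0,1]`.
#' @param alpha_tau,beta_tau Beta concentration parameters (> 0).
#' @param sigma_eps noise level (> 0).
#' @param b shift (>= 0).
#' @param rho slope (> 0).
#' @return list of class `buds_params`.
#' @export
buds_params <- function(tau, alpha_tau = 1, beta_tau = 1, sigma_eps = 0.2,
                        b = 0.05, rho = 1) {
  structure(list(tau = as.numeric(tau), alpha_tau = alpha_tau,
                 beta_tau = beta_tau, sigma_eps = sigma_eps, b = b, rho = rho),
            class = "buds_params")
}

params_in_support <- function(p) {
  all(is.finite(c(p$tau, p$alpha_tau, p$beta_tau, p$sigma_eps, p$b, p$rho))) &&
    all(p$tau >= 0 & p$tau <= 1) && p$alpha_tau > 0 && p$beta_tau > 0 &&
    p$sigma_eps > 0 && p$b >= 0 && p$rho > 0
}

## log density of Cauchy(center, scale) truncated to (0, Inf)
log_half_cauchy <- function(x, center, scale) {
  logZ <- log(0.5 + atan(center / scale) / pi)
  stats::dcauchy(x, center, scale, log = TRUE) - logZ
}

## d/dx of log half-Cauchy density (normalizer does not depend on x)
dlog_half_cauchy <- function(x, center, scale) {
  -2 * (x - center) / (scale^2 + (x - center)^2)
}

## Precompute pair bookkeeping shared by log-joint and gradient evaluations.
pair_cache <- function(D, S) {
  n <- nrow(D)
  up <- which(upper.tri(D))
  ii <- row(D)[up]; jj <- col(D)[up]
  d <- D[up]
  if (any(d <= 0))
    stop("off-diagonal zero dissimilarities found (exact duplicates); ",
         "deduplicate the samples or floor the dissimilarities before fitting")
  list(n = n, ii = ii, jj = jj, d = d, logd = log(d), s2 = S[up],
       grp = c(ii, jj))
}

## Value (and optionally gradient wrt constrained parameters) of the log joint.
## theta: list(tau, alpha_tau, beta_tau, sigma_eps, b, rho)
log_joint_core <- function(theta, cache, hyper, grad = FALSE) {
  tau <- theta$tau; at <- theta$alpha_tau; bt <- theta$beta_tau
  se <- theta$sigma_eps; b <- theta$b; rho <- theta$rho
  n <- cache$n
  dtau <- tau[cache$ii] - tau[cache$jj]
  delta <- abs(dtau)
  mu_raw <- if (hyper$use_shift_scale) b + rho * delta else delta
  floored <- mu_raw < hyper$mu_floor
  mu <- pmax(mu_raw, hyper$mu_floor)
  v <- cache$s2 * se^2
  a <- mu^2 / v
  rate <- mu / v
  ## Gamma log-likelihood of observed dissimilarities
  ll <- sum(a * log(rate) - lgamma(a) + (a - 1) * cache$logd - rate * cache$d)
  ## Beta prior on tau (guard exact 0/1 for the log)
  taus <- pmin(pmax(tau, 1e-12), 1 - 1e-12)
  lbeta_term <- sum((at - 1) * log(taus) + (bt - 1) * log1p(-taus)) -
    n * lbeta(at, bt)
  lp <- log_half_cauchy(at, 1, hyper$gamma_tau) +
    log_half_cauchy(bt, 1, hyper$gamma_tau) +
    log_half_cauchy(se, 0, hyper$gamma_eps)
  if (hyper$use_shift_scale)
    lp <- lp + log_half_cauchy(b, 0, hyper$gamma_b) +
      log_half_cauchy(rho, 1, hyper$gamma_rho)
  value <- ll + lbeta_term + lp
  if (!grad) return(list(value = value))

  w1 <- log(rate) - digamma(a) + cache$logd
  dLdmu <- (2 * mu / v) * w1 + (mu - cache$d) / v
  dLdv <- -(mu^2 / v^2) * w1 - mu * (mu - cache$d) / v^2
  dLdmu[floored] <- 0
  sgn <- sign(dtau)
  gpair <- dLdmu * (if (hyper$use_shift_scale) rho else 1) * sgn
  gtau_lik <- as.vector(rowsum(c(gpair, -gpair), cache$grp))
  gtau <- gtau_lik + (at - 1) / taus - (bt - 1) / (1 - taus)
  dig_ab <- digamma(at + bt)
  gat <- sum(log(taus)) - n * (digamma(at) - dig_ab) +
    dlog_half_cauchy(at, 1, hyper$gamma_tau)
  gbt <- sum(log1p(-taus)) - n * (digamma(bt) - dig_ab) +
    dlog_half_cauchy(bt, 1, hyper$gamma_tau)
  gse <- sum(dLdv * 2 * cache$s2 * se) +
    dlog_half_cauchy(se, 0, hyper$gamma_eps)
  if (hyper$use_shift_scale) {
    gb <- sum(dLdmu) + dlog_half_cauchy(b, 0, hyper$gamma_b)
    grho <- sum(dLdmu * delta) + dlog_half_cauchy(rho, 1, hyper$gamma_rho)
  } else {
    gb <- 0; grho <- 0
  }
  list(value = value,
       grad = list(tau = gtau, alpha_tau = gat, beta_tau = gbt,
                   sigma_eps = gse, b = gb, rho = grho))
}

#' Log joint density of the BUDS model
#'
#' Evaluates, up to nothing (all normalizing constants included):
#' \deqn{\sum_{i<j} \log Gamma(d_{ij};\, \alpha_{ij}, \beta_{ij})
#'   + \sum_i \log Beta(\tau_i;\, \alpha_\tau, \beta_\tau)
#'   + \log priors,}
#' where \eqn{(\alpha_{ij}, \beta_{ij})} = [gamma_shape_rate()] of the mean
#' [expected_dissimilarity()] and variance \eqn{s^2_{ij} \sigma_\epsilon^2},
#' and the hyperpriors are half-Cauchy: \eqn{\alpha_\tau, \beta_\tau \sim
#' Cauchy^+(1, \gamma_\tau)}, \eqn{\rho \sim Cauchy^+(1, \gamma_\rho)},
#' \eqn{b \sim Cauchy^+(0, \gamma_b)}, \eqn{\sigma_\epsilon \sim
#' Cauchy^+(0, \gamma_\epsilon)}, each with its truncation normalizer.
#' Returns `-Inf` (not an error) for parameters outside the support, so the
#' function can be handed directly to samplers.
#'
#' @param params [buds_params()] realization.
#' @param D dissimilarity matrix with strictly positive off-diagonal entries.
#' @param S noise scales ([knn_variance_scales()], [uniform_scales()] or
#'   matrix).
#' @param hyper [buds_hyperparams()].
#' @return scalar log density.
#' @export
buds_log_joint <- function(params, D, S, hyper = buds_hyperparams()) {
  D <- check_dissimilarity(D)
  S <- as_scales_matrix(S, D)
  if (length(params$tau) != nrow(D))
    stop("length(tau) must equal nrow(D)")
  if (!params_in_support(params)) return(-Inf)
  cache <- pair_cache(D, S)
  log_joint_core(params, cache, hyper)$value
}
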