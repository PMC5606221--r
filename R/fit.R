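#' Fit the BUDS model to a dissimilarity matrix
#'
#' Infers latent one-dimensional coordinates \eqn{\tau \in [0,1]} (plus the
#' Beta concentration parameters, the noise level \eqn{\sigma_\epsilon} and,
#' under the shift/scale transform, \eqn{b} and \eqn{\rho}) from pairwise
#' dissimilarities, by mean-field automatic-differentiation variational
#' inference in the unconstrained space (`backend = "advi"`, the default) or
#' by adaptive random-walk Metropolis (`backend = "mcmc"`).
#'
#' The latent ordering is identified only up to reflection
#' \eqn{\tau \mapsto 1 - \tau}; after fitting, the draws are oriented so the
#' posterior mean of \eqn{\tau} correlates non-negatively with the first
#' principal coordinate of `D` (see [orient_draws()]). The point estimate is
#' the posterior mean of the oriented draws (for a Gaussian variational family
#' this coincides with the mode in the unconstrained space).
#'
#' @param D symmetric dissimilarity matrix with strictly positive
#'   off-diagonal entries (exact duplicate samples must be collapsed first).
#' @param scales noise scales ([knn_variance_scales()] result, matrix, or
#'   `NULL` to compute KNN scales with neighborhood size `K`).
#' @param K neighborhood size used when `scales` is `NULL` (default 10).
#' @param hyper [buds_hyperparams()].
#' @param draws number of posterior draws to return (>= 100 recommended).
#' @param seed integer seed; identical (seed, backend, inputs) give
#'   bitwise-identical results.
#' @param backend `"advi"` or `"mcmc"`.
#' @param mass HPD interval probability mass for summaries (default 0.95).
#' @param control backend options. ADVI: `max_iter` (8000), `mc_samples` (2),
#'   `lr` (0.05), `tol` (1e-4), `patience` (100). MCMC: `warmup` (2000),
#'   `thin` (5), `step0`.
#' @return object of class `buds` with posterior draws, oriented point
#'   estimates, HPD intervals and diagnostics. Use `print`, `summary`,
#'   `coef`, `plot`, `fitted`, `residuals`, `simulate`.
#' @seealso [summary.buds()], [hpdi()], [simulate.buds()]
#' @export
#' @examples
#' sim <- generate_model_draw(n = 15, sigma_eps = 0.1, seed = 1)
#' fit <- buds(sim$D, scales = uniform_scales(sim$D), draws = 100, seed = 1,
#'             control = list(max_iter = 1500))
#' cor(coef(fit), sim$tau_true, method = "spearman")
buds <- function(D, scales = NULL, K = 10, hyper = buds_hyperparams(),
                 draws = 500, seed = 1, backend = c("advi", "mcmc"),
                 mass = 0.95, control = list()) {
  backend <- match.arg(backend)
  D <- check_dissimilarity(D)
  S <- as_scales_matrix(scales, D, K = K)
  if (draws < 2) stop("'draws' must be at least 2")
  n <- nrow(D)
  cache <- pair_cache(D, S)
  lay <- unconstrain_layout(n, hyper$use_shift_scale)
  set.seed(as.integer(seed))
  res <- if (backend == "advi") run_advi(cache, lay, hyper, D, draws, control)
         else run_mcmc(cache, lay, hyper, D, draws, control)
  ## constrained-scale draws
  tau_draws <- stats::plogis(res$U[, lay$tau, drop = FALSE])
  colnames(tau_draws) <- rownames(D)
  scalars <- data.frame(
    alpha_tau = exp(res$U[, lay$at]),
    beta_tau = exp(res$U[, lay$bt]),
    sigma_eps = exp(res$U[, lay$se]),
    b = if (lay$shift) exp(res$U[, lay$b]) else 0,
    rho = if (lay$shift) exp(res$U[, lay$rho]) else 1)
  ori <- orient_draws(tau_draws, D)
  fit <- structure(list(
    tau_draws = ori$draws, scalar_draws = scalars,
    D = D, S = S, hyper = hyper, n = n, draws = nrow(ori$draws),
    seed = as.integer(seed), backend = backend, mass = mass,
    elbo = res$elbo, converged = res$converged,
    accept_rate = res$accept_rate %||% NA_real_,
    flipped = ori$flipped), class = "buds")
  est <- summarize_draws(fit, mass)
  fit$tau_hat <- est$tau_hat
  fit$hpdi_low <- est$hpdi_low
  fit$hpdi_high <- est$hpdi_high
  fit
}

#' Highest posterior density interval of a draw vector
#'
#' The narrowest contiguous interval of the sorted draws containing
#' `ceiling(mass * T)` of them.
#'
#' @param samples numeric vector of posterior draws.
#' @param mass probability mass in (0, 1].
#' @return named numeric vector `c(low, high)`.
#' @export
#' @examples
#' hpdi(c(0, 0.1, 0.11, 0.12, 0.9), 0.6)  # c(0.10, 0.12)
hpdi <- function(samples, mass = 0.95) {
  if (length(samples) == 0L) stop("empty draw vector")
  if (mass <= 0 || mass > 1) stop("'mass' must be in (0, 1]")
  xs <- sort(samples)
  T <- length(xs)
  w <- ceiling(mass * T)
  if (w >= T) return(c(low = xs[1], high = xs[T]))
  widths <- xs[w:T] - xs[1:(T - w + 1)]
  i <- which.min(widths)
  c(low = xs[i], high = xs[i + w - 1])
}

#' Fix the reflection of posterior draws
#'
#' The model is invariant under \eqn{\tau \mapsto 1 - \tau}. This resolves the
#' reflection deterministically: if the Spearman correlation between the
#' posterior mean of \eqn{\tau} and the first principal coordinate of `D` is
#' negative, every draw is replaced by \eqn{1 - \tau}.
#'
#' @param tau_draws T x n matrix of draws.
#' @param D the dissimilarity matrix the model was fitted to.
#' @return list with `draws` (possibly flipped) and `flipped` (logical).
#' @export
orient_draws <- function(tau_draws, D) {
  D <- check_dissimilarity(D)
  pc1 <- tryCatch(stats::cmdscale(D, k = 1)[, 1], error = function(e) NULL)
  if (is.null(pc1) || stats::sd(pc1) == 0) {
    warning("first principal coordinate has zero variance; ",
            "orientation left unchanged")
    return(list(draws = tau_draws, flipped = FALSE))
  }
  m <- colMeans(tau_draws)
  r <- stats::cor(m, pc1, method = "spearman")
  if (!is.na(r) && r < 0) list(draws = 1 - tau_draws, flipped = TRUE)
  else list(draws = tau_draws, flipped = FALSE)
}

summarize_draws <- function(object, mass) {
  tau_hat <- colMeans(object$tau_draws)
  H <- apply(object$tau_draws, 2, hpdi, mass = mass)
  list(tau_hat = tau_hat, hpdi_low = H["low", ], hpdi_high = H["high", ])
}

#' @export
print.buds <- function(x, ...) {
  cat(sprintf("BUDS fit: n = %d samples, %d posterior draws (%s backend)\n",
              x$n, x$draws, x$backend))
  cat(sprintf("  sigma_eps: %.3f   b: %.3f   rho: %.3f   (posterior means)\n",
              mean(x$scalar_draws$sigma_eps), mean(x$scalar_draws$b),
              mean(x$scalar_draws$rho)))
  if (x$backend == "advi")
    cat(sprintf("  final ELBO: %.2f  (converged: %s)\n",
                tail(x$elbo, 1), x$converged))
  else
    cat(sprintf("  Metropolis acceptance rate: %.2f\n", x$accept_rate))
  invisible(x)
}

#' Summarize a BUDS fit
#'
#' Per-sample point estimate (posterior mean of the oriented draws, reported
#' as the mode-\eqn{\tau}), its rank, and HPD interval bounds.
#'
#' @param object a `buds` fit.
#' @param mass HPD mass (defaults to the mass stored in the fit).
#' @param ... unused.
#' @return data.frame of class `summary.buds` with columns `sample_id`,
#'   `tau_hat`, `rank`, `hpdi_low`, `hpdi_high`.
#' @export
summary.buds <- function(object, mass = object$mass, ...) {
  est <- if (identical(mass, object$mass))
    list(tau_hat = object$tau_hat, hpdi_low = object$hpdi_low,
         hpdi_high = object$hpdi_high)
  else summarize_draws(object, mass)
  out <- data.frame(sample_id = colnames(object$tau_draws),
                    tau_hat = unname(est$tau_hat),
                    rank = rank(unname(est$tau_hat), ties.method = "first"),
                    hpdi_low = unname(est$hpdi_low),
                    hpdi_high = unname(est$hpdi_high),
                    row.names = NULL)
  attr(out, "mass") <- mass
  class(out) <- c("summary.buds", "data.frame")
  out
}

#' @export
print.summary.buds <- function(x, ...) {
  cat(sprintf("Latent ordering estimate (%.0f%% HPDI):\n",
              100 * attr(x, "mass")))
  print.data.frame(head(x[order(x$tau_hat), ], 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more samples\n")
  invisible(x)
}

#' @export
coef.buds <- function(object, ...) object$tau_hat

#' @export
fitted.buds <- function(object, ...) {
  p <- buds_params(object$tau_hat,
                   alpha_tau = mean(object$scalar_draws$alpha_tau),
                   beta_tau = mean(object$scalar_draws$beta_tau),
                   sigma_eps = mean(object$scalar_draws$sigma_eps),
                   b = mean(object$scalar_draws$b),
                   rho = mean(object$scalar_draws$rho))
  n <- object$n
  M <- matrix(0, n, n, dimnames = dimnames(object$D))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    M[i, j] <- M[j, i] <- expected_dissimilarity(p, i, j, object$hyper)
  M
}

#' @export
residuals.buds <- function(object, ...) object$D - fitted(object)

#' Plot the latent ordering with uncertainty
#'
#' Scatter of \eqn{\hat\tau} against its rank with HPD interval whiskers — the
#' standard ordering view. Steep stretches indicate sparsely sampled regions
#' of the gradient.
#'
#' @param x a `buds` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.buds <- function(x, ...) {
  s <- summary(x)
  o <- order(s$tau_hat)
  plot(seq_along(o), s$tau_hat[o], ylim = c(0, 1),
       xlab = "rank(tau)", ylab = "tau", pch = 19, ...)
  segments(seq_along(o), s$hpdi_low[o], seq_along(o), s$hpdi_high[o],
           col = "grey60")
  invisible(s)
}

#' Write the per-sample ordering table and draws to TSV
#'
#' @param fit a `buds` fit.
#' @param prefix output path prefix; writes `<prefix>.tau.tsv` (summary table),
#'   `<prefix>.draws.tsv` (long format: draw, sample_id, tau) and
#'   `<prefix>.scalars.tsv`.
#' @return invisibly, the paths written.
#' @export
write_buds_fit <- function(fit, prefix) {
  p1 <- paste0(prefix, ".tau.tsv")
  write.table(summary(fit), p1, sep = "\t", quote = FALSE, row.names = FALSE)
  long <- data.frame(
    draw = rep(seq_len(fit$draws), times = fit$n),
    sample_id = rep(colnames(fit$tau_draws), each = fit$draws),
    tau = as.vector(fit$tau_draws))
  p2 <- paste0(prefix, ".draws.tsv")
  write.table(long, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- paste0(prefix, ".scalars.tsv")
  write.table(cbind(draw = seq_len(fit$draws), fit$scalar_draws), p3,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
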