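## Mean-field ADVI and random-walk Metropolis over the unconstrained space.
##
## Unconstrained vector u = (u_tau[1..n], u_alpha, u_beta, u_sigma[, u_b, u_rho]):
## tau = logistic(u_tau), every positive parameter = exp(u). The target is
## g(u) = log_joint(theta(u)) + log |d theta / d u|.

unconstrain_layout <- function(n, shift) {
  k <- n + 3L + if (shift) 2L else 0L
  list(n = n, dim = k, tau = seq_len(n), at = n + 1L, bt = n + 2L,
       se = n + 3L, b = if (shift) n + 4L else NA_integer_,
       rho = if (shift) n + 5L else NA_integer_, shift = shift)
}

u_to_theta <- function(u, lay) {
  tau <- stats::plogis(u[lay$tau])
  list(tau = tau,
       alpha_tau = exp(u[lay$at]), beta_tau = exp(u[lay$bt]),
       sigma_eps = exp(u[lay$se]),
       b = if (lay$shift) exp(u[lay$b]) else 0,
       rho = if (lay$shift) exp(u[lay$rho]) else 1)
}

## value and gradient of g(u)
target_u <- function(u, lay, cache, hyper, grad = TRUE) {
  th <- u_to_theta(u, lay)
  res <- log_joint_core(th, cache, hyper, grad = grad)
  tau <- th$tau
  ljac <- sum(log(tau) + log1p(-tau)) +
    u[lay$at] + u[lay$bt] + u[lay$se] +
    (if (lay$shift) u[lay$b] + u[lay$rho] else 0)
  out <- list(value = res$value + ljac)
  if (grad) {
    g <- numeric(lay$dim)
    g[lay$tau] <- res$grad$tau * tau * (1 - tau) + (1 - 2 * tau)
    g[lay$at] <- res$grad$alpha_tau * th$alpha_tau + 1
    g[lay$bt] <- res$grad$beta_tau * th$beta_tau + 1
    g[lay$se] <- res$grad$sigma_eps * th$sigma_eps + 1
    if (lay$shift) {
      g[lay$b] <- res$grad$b * th$b + 1
      g[lay$rho] <- res$grad$rho * th$rho + 1
    }
    out$grad <- g
  }
  out
}

## Warm start: rank-map the first principal coordinate of D into (0,1)
init_unconstrained <- function(D, cache, lay) {
  n <- lay$n
  u0 <- numeric(lay$dim)
  pc1 <- tryCatch(stats::cmdscale(D, k = 1)[, 1], error = function(e) NULL)
  if (is.null(pc1) || stats::sd(pc1) == 0) {
    u0[lay$tau] <- stats::qlogis((seq_len(n) - 0.5) / n)
  } else {
    u0[lay$tau] <- stats::qlogis((rank(pc1, ties.method = "first") - 0.5) / n)
  }
  u0[lay$at] <- 0; u0[lay$bt] <- 0
  u0[lay$se] <- log(0.3)
  if (lay$shift) {
    dmin <- min(cache$d); dmax <- max(cache$d)
    u0[lay$b] <- log(max(dmin, 1e-3))
    u0[lay$rho] <- log(max(dmax - dmin, 0.1))
  }
  u0
}

run_advi <- function(cache, lay, hyper, D, draws, control) {
  ctl <- modifyList(list(max_iter = 8000L, mc_samples = 2L, lr = 0.05,
                         tol = 1e-4, patience = 100L, check_every = 100L,
                         sd_init = -2), control)
  m <- init_unconstrained(D, cache, lay)
  om <- rep(ctl$sd_init, lay$dim)
  ## Adam state
  a_m1 <- a_v1 <- numeric(lay$dim); a_m2 <- a_v2 <- numeric(lay$dim)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  elbo_trace <- numeric(0)
  best <- -Inf; stall <- 0L; converged <- FALSE
  prev_win <- NA_real_
  for (it in seq_len(ctl$max_iter)) {
    gm <- numeric(lay$dim); gw <- numeric(lay$dim); val <- 0
    for (s in seq_len(ctl$mc_samples)) {
      z <- stats::rnorm(lay$dim)
      u <- m + exp(om) * z
      tg <- target_u(u, lay, cache, hyper)
      if (!is.finite(tg$value)) { tg$value <- -1e10; tg$grad[] <- 0 }
      val <- val + tg$value
      gm <- gm + tg$grad
      gw <- gw + tg$grad * z * exp(om)
    }
    gm <- gm / ctl$mc_samples
    gw <- gw / ctl$mc_samples + 1     # + d entropy / d omega
    elbo_trace[it] <- val / ctl$mc_samples + sum(om)
    ## Adam ascent
    a_m1 <- b1 * a_m1 + (1 - b1) * gm
    a_v1 <- b2 * a_v1 + (1 - b2) * gm^2
    a_m2 <- b1 * a_m2 + (1 - b1) * gw
    a_v2 <- b2 * a_v2 + (1 - b2) * gw^2
    corr <- sqrt(1 - b2^it) / (1 - b1^it)
    m <- m + ctl$lr * corr * a_m1 / (sqrt(a_v1) + eps)
    om <- om + ctl$lr * corr * a_m2 / (sqrt(a_v2) + eps)
    if (it %% ctl$check_every == 0L) {
      win <- mean(elbo_trace[(it - ctl$check_every + 1L):it])
      if (!is.na(prev_win)) {
        rel <- abs(win - prev_win) / (abs(prev_win) + 1e-8)
        if (rel < ctl$tol) stall <- stall + ctl$check_every else stall <- 0L
        if (stall >= ctl$patience) { converged <- TRUE; break }
      }
      prev_win <- win
    }
  }
  if (!converged)
    warning("ADVI reached max_iter without meeting the ELBO tolerance; ",
            "inspect the elbo trace", call. = FALSE)
  ## draws from the fitted mean-field Gaussian
  Z <- matrix(stats::rnorm(draws * lay$dim), draws, lay$dim)
  U <- sweep(Z, 2, exp(om), "*")
  U <- sweep(U, 2, m, "+")
  list(U = U, m = m, omega = om, elbo = elbo_trace, converged = converged)
}

## Metropolis-adjusted Langevin sampler, warm-started and diagonally
## preconditioned by a short variational run. Every third iteration proposes a
## symmetric random-walk step along one of two fixed "ridge" directions in the
## unconstrained space — a common logit shift of all tau, and a spread around
## their warm-start center. These directions track the near-flat
## translation/scale mode of the posterior (the likelihood constrains tau only
## through b + rho |tau_i - tau_j|), which gradient steps alone traverse very
## slowly; mixing over the ridge is what makes credible intervals honest.
run_mcmc <- function(cache, lay, hyper, D, draws, control) {
  ctl <- modifyList(list(warmup = 4000L, thin = 10L, step0 = 0.5,
                         ridge_step0 = 1, precondition_iter = 2000L), control)
  pre <- suppressWarnings(run_advi(cache, lay, hyper, D, draws = 2L,
                                   control = list(max_iter =
                                                    ctl$precondition_iter)))
  u <- pre$m
  Md <- exp(2 * pre$omega)            # diagonal preconditioner
  sqM <- sqrt(Md)
  n <- lay$n
  v1 <- c(rep(1, n), rep(0, lay$dim - n))
  v1 <- v1 / sqrt(sum(v1^2))
  mt <- pre$m[lay$tau]
  v2 <- c(mt - mean(mt), rep(0, lay$dim - n))
  if (sum(v2^2) < 1e-12) v2 <- v1 else v2 <- v2 / sqrt(sum(v2^2))
  f <- function(u) target_u(u, lay, cache, hyper)
  cur <- f(u)
  lstep <- log(ctl$step0); lridge <- log(ctl$ridge_step0)
  n_total <- ctl$warmup + draws * ctl$thin
  keep <- matrix(NA_real_, draws, lay$dim)
  ki <- 0L; acc <- 0L
  for (it in seq_len(n_total)) {
    if (it %% 3L == 0L) {
      v <- if (it %% 2L == 0L) v1 else v2
      prop <- u + exp(lridge) * stats::rnorm(1) * v
      pv <- f(prop)
      a <- if (is.finite(pv$value)) pv$value - cur$value else -Inf
      accepted <- log(stats::runif(1)) < a
      if (accepted) { u <- prop; cur <- pv; acc <- acc + 1L }
      if (it <= ctl$warmup)
        lridge <- lridge + it^(-0.6) * ((if (accepted) 1 else 0) - 0.44)
    } else {
      e2 <- exp(2 * lstep)
      mu_fwd <- u + 0.5 * e2 * Md * cur$grad
      prop <- mu_fwd + exp(lstep) * sqM * stats::rnorm(lay$dim)
      pv <- f(prop)
      if (is.finite(pv$value)) {
        mu_bwd <- prop + 0.5 * e2 * Md * pv$grad
        lq_fwd <- -sum((prop - mu_fwd)^2 / (e2 * Md)) / 2
        lq_bwd <- -sum((u - mu_bwd)^2 / (e2 * Md)) / 2
        a <- pv$value - cur$value + lq_bwd - lq_fwd
      } else a <- -Inf
      accepted <- log(stats::runif(1)) < a
      if (accepted) { u <- prop; cur <- pv; acc <- acc + 1L }
      if (it <= ctl$warmup)
        lstep <- lstep + it^(-0.6) * ((if (accepted) 1 else 0) - 0.574)
    }
    if (it > ctl$warmup && (it - ctl$warmup) %% ctl$thin == 0L) {
      ki <- ki + 1L
      keep[ki, ] <- u
    }
  }
  list(U = keep, m = colMeans(keep), omega = log(apply(keep, 2, stats::sd)),
       elbo = pre$elbo, converged = TRUE,
       accept_rate = acc / n_total)
}
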