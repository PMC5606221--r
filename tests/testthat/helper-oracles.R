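## Independent straight-from-definition oracles used to check the package's
## optimized implementations. Deliberately literal and slow.

## KNN variance scales: enumerate neighbor sets and the distance set
## D^K_ij = {d(x_i, x_k): x_k in G_K(x_j) \ {x_i}} u
##          {d(x_j, x_l): x_l in G_K(x_i) \ {x_j}}
oracle_knn_scales <- function(D, K) {
  n <- nrow(D)
  nbrs <- function(i) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    ord[1:K]
  }
  raw <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dset <- c()
    for (k in nbrs(j)) if (k != i) dset <- c(dset, D[i, k])
    for (l in nbrs(i)) if (l != j) dset <- c(dset, D[j, l])
    raw[i, j] <- raw[j, i] <- var(dset)
  }
  up <- upper.tri(raw)
  fl <- pmax(raw, 1e-6 * mean(D[up])^2)
  s2 <- fl / mean(fl[up])
  diag(s2) <- 0
  s2
}

## log joint: explicit per-term sum with textbook densities
oracle_log_joint <- function(params, D, S, hyper = buds_hyperparams()) {
  n <- nrow(D)
  lhc <- function(x, c, g)
    dcauchy(x, c, g, log = TRUE) - log(1 - pcauchy(0, c, g))
  total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    del <- abs(params$tau[i] - params$tau[j])
    mu <- if (hyper$use_shift_scale) params$b + params$rho * del else del
    mu <- max(hyper$mu_floor, mu)
    v <- S[i, j] * params$sigma_eps^2
    total <- total + dgamma(D[i, j], shape = mu^2 / v, rate = mu / v,
                            log = TRUE)
  }
  total <- total +
    sum(dbeta(params$tau, params$alpha_tau, params$beta_tau, log = TRUE)) +
    lhc(params$alpha_tau, 1, hyper$gamma_tau) +
    lhc(params$beta_tau, 1, hyper$gamma_tau) +
    lhc(params$sigma_eps, 0, hyper$gamma_eps)
  if (hyper$use_shift_scale)
    total <- total + lhc(params$b, 0, hyper$gamma_b) +
      lhc(params$rho, 1, hyper$gamma_rho)
  total
}

## HPDI: try every contiguous window of ceiling(mass * T) sorted samples
oracle_hpdi <- function(x, mass) {
  xs <- sort(x)
  T <- length(xs)
  w <- ceiling(mass * T)
  best <- c(xs[1], xs[T]); bw <- Inf
  for (i in 1:(T - w + 1)) {
    width <- xs[i + w - 1] - xs[i]
    if (width < bw) { bw <- width; best <- c(xs[i], xs[i + w - 1]) }
  }
  best
}

## DiSTATIS from its definition, scalar loops only
oracle_distatis <- function(slices, k = 2) {
  t <- length(slices); n <- nrow(slices[[1]])
  J <- diag(n) - matrix(1 / n, n, n)
  Ss <- lapply(slices, function(D) {
    S <- -0.5 * J %*% (D^2) %*% J
    S / eigen(S, symmetric = TRUE)$values[1]
  })
  C <- matrix(0, t, t)
  for (a in 1:t) for (b in 1:t)
    C[a, b] <- sum(diag(Ss[[a]] %*% Ss[[b]])) /
      sqrt(sum(diag(Ss[[a]] %*% Ss[[a]])) * sum(diag(Ss[[b]] %*% Ss[[b]])))
  alpha <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(alpha) < 0) alpha <- -alpha
  alpha <- pmax(alpha, 0); alpha <- alpha / sum(alpha)
  Splus <- matrix(0, n, n)
  for (s in 1:t) Splus <- Splus + alpha[s] * Ss[[s]]
  es <- eigen(Splus, symmetric = TRUE)
  V <- es$vectors[, 1:k, drop = FALSE]
  lam <- es$values[1:k]
  list(alpha = alpha,
       consensus = V %*% diag(sqrt(lam), k),
       compromise = Splus)
}

## quick random dissimilarity matrix from points on a line
line_dissimilarity <- function(x) {
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", seq_along(x)), paste0("s", seq_along(x)))
  D
}

expect_valid_dissimilarity <- function(D) {
  expect_true(is.matrix(D))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
}
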