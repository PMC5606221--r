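test_that("hpdi matches the all-windows oracle and its closed cases", {
  expect_equal(unname(hpdi(c(0, 0.1, 0.11, 0.12, 0.9), 0.6)), c(0.1, 0.12))
  expect_equal(unname(hpdi(rep(0.4, 10), 0.9)), c(0.4, 0.4))
  x <- c(3, 1, 7, 2)
  expect_equal(unname(hpdi(x, 1)), c(1, 7))
  set.seed(41)
  for (rep in 1:10) {
    T <- sample(5:200, 1)
    x <- rnorm(T)
    mass <- runif(1, 0.3, 0.99)
    expect_equal(unname(hpdi(x, mass)), oracle_hpdi(x, mass))
  }
  expect_error(hpdi(numeric(0)), "empty")
})

test_that("fitting is bitwise deterministic for a fixed seed and backend", {
  sim <- generate_model_draw(n = 15, sigma_eps = 0.2, seed = 8)
  ctl <- list(max_iter = 800)
  f1 <- suppressWarnings(
    buds(sim$D, uniform_scales(sim$D), draws = 80, seed = 4, control = ctl))
  f2 <- suppressWarnings(
    buds(sim$D, uniform_scales(sim$D), draws = 80, seed = 4, control = ctl))
  expect_identical(f1$tau_draws, f2$tau_draws)
  expect_identical(coef(f1), coef(f2))
  m1 <- buds(sim$D, uniform_scales(sim$D), draws = 40, seed = 4,
             backend = "mcmc",
             control = list(warmup = 300, thin = 2, precondition_iter = 300))
  m2 <- buds(sim$D, uniform_scales(sim$D), draws = 40, seed = 4,
             backend = "mcmc",
             control = list(warmup = 300, thin = 2, precondition_iter = 300))
  expect_identical(m1$tau_draws, m2$tau_draws)
})

test_that("near-noiseless dissimilarities are ordered almost perfectly", {
  sim <- generate_model_draw(n = 20, b = 0.05, rho = 1, sigma_eps = 0.02,
                             seed = 2)
  fit <- suppressWarnings(
    buds(sim$D, uniform_scales(sim$D), draws = 200, seed = 1))
  expect_gte(abs(cor(coef(fit), sim$tau_true, method = "spearman")), 0.99)
})

test_that("orientation is an involution aligned with the first principal coordinate", {
  sim <- generate_model_draw(n = 15, sigma_eps = 0.15, seed = 9)
  fit <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 100,
                               seed = 1, control = list(max_iter = 1500)))
  pc1 <- cmdscale(sim$D, k = 1)[, 1]
  ## after orientation the alignment is non-negative
  expect_gte(cor(coef(fit), pc1, method = "spearman"), 0)
  ## already-aligned draws come back unchanged; flipped draws get restored
  o1 <- orient_draws(fit$tau_draws, sim$D)
  expect_identical(o1$draws, fit$tau_draws)
  expect_false(o1$flipped)
  o2 <- orient_draws(1 - fit$tau_draws, sim$D)
  expect_true(o2$flipped)
  expect_equal(o2$draws, fit$tau_draws, tolerance = 1e-12)
})

test_that("summaries are means and HPD bounds of the draws, equivariant to relabeling", {
  fit <- structure(list(
    tau_draws = rbind(c(0.2, 0.8), c(0.4, 0.6)),
    mass = 1, n = 2, draws = 2), class = "buds")
  colnames(fit$tau_draws) <- c("a", "b")
  fit$tau_hat <- colMeans(fit$tau_draws)
  H <- apply(fit$tau_draws, 2, hpdi, mass = 1)
  fit$hpdi_low <- H["low", ]; fit$hpdi_high <- H["high", ]
  s <- summary(fit)
  expect_equal(s$tau_hat, c(0.3, 0.7))
  expect_equal(s$hpdi_low, c(0.2, 0.6))
  expect_equal(s$hpdi_high, c(0.4, 0.8))
  ## constant draws reproduce the constant with zero-width intervals
  fitc <- fit
  fitc$tau_draws <- rbind(c(0.5, 0.25), c(0.5, 0.25))
  colnames(fitc$tau_draws) <- c("a", "b")
  fitc$tau_hat <- colMeans(fitc$tau_draws)
  Hc <- apply(fitc$tau_draws, 2, hpdi, mass = 1)
  fitc$hpdi_low <- Hc["low", ]; fitc$hpdi_high <- Hc["high", ]
  sc <- summary(fitc)
  expect_equal(sc$tau_hat, sc$hpdi_low)
  expect_equal(sc$tau_hat, sc$hpdi_high)
  ## relabeling samples permutes the summary rows consistently
  sim <- generate_model_draw(n = 12, sigma_eps = 0.2, seed = 3)
  f <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 60,
                             seed = 2, control = list(max_iter = 800)))
  perm <- c(5, 1, 12, 3, 9, 2, 11, 4, 10, 6, 8, 7)
  fp <- suppressWarnings(buds(sim$D[perm, perm],
                              uniform_scales(sim$D[perm, perm]), draws = 60,
                              seed = 2, control = list(max_iter = 800)))
  expect_equal(cor(coef(f)[perm], coef(fp)), 1, tolerance = 0.05)
})

test_that("posterior intervals for tau_true reach the coverage floor with the sampler", {
  cov <- sapply(1:3, function(s) {
    sim <- generate_model_draw(n = 20, sigma_eps = 0.3, seed = 400 + s)
    fit <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 800,
                                 seed = s, backend = "mcmc"))
    tt <- sim$tau_true
    if (cor(coef(fit), tt, method = "spearman") < 0) tt <- 1 - tt
    mean(tt >= fit$hpdi_low & tt <= fit$hpdi_high)
  })
  expect_gte(mean(cov), 0.8)
})

test_that("fitted and residual methods reconstruct the expected dissimilarities", {
  sim <- generate_model_draw(n = 12, sigma_eps = 0.1, seed = 6)
  fit <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 100,
                               seed = 1, control = list(max_iter = 1500)))
  Fm <- fitted(fit)
  expect_valid_dissimilarity(round(Fm - diag(diag(Fm)), 12))
  expect_equal(sim$D - Fm, residuals(fit))
  ## low noise: fitted means should track the data closely
  up <- upper.tri(Fm)
  expect_lt(mean(abs(residuals(fit)[up])), 0.15)
})

test_that("the fit table round-trips through write_buds_fit", {
  sim <- generate_model_draw(n = 10, sigma_eps = 0.2, seed = 10)
  fit <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 50,
                               seed = 1, control = list(max_iter = 500)))
  pre <- file.path(tempdir(), "run1")
  paths <- write_buds_fit(fit, pre)
  tab <- read.delim(paths[1])
  expect_equal(tab$tau_hat, unname(coef(fit)), tolerance = 1e-6)
  draws <- read.delim(paths[2])
  expect_equal(nrow(draws), fit$draws * fit$n)
})
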