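test_that("classical scaling reproduces Euclidean configurations (Gower)", {
  ## collinear points: first axis recovers the line, higher eigenvalues ~ 0
  x <- c(0, 1, 2, 4)
  D <- line_dissimilarity(x)
  em <- pcoa(D, k = 1)
  expect_equal(as.matrix(dist(em$coords)), unname(D), tolerance = 1e-8,
               ignore_attr = TRUE)
  full <- suppressWarnings(pcoa(D, k = 3))
  expect_lt(sum(abs(full$eigenvalues[-1])), 1e-8)
  ## random planar/3D configurations: pairwise distances reproduced
  set.seed(61)
  for (rep in 1:4) {
    n <- sample(5:50, 1); k <- sample(2:3, 1)
    P <- matrix(rnorm(n * k), n)
    D <- as.matrix(dist(P))
    em <- pcoa(D, k = k)
    expect_equal(as.matrix(dist(em$coords)), D, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("three equidistant points give two equal positive eigenvalues", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  em <- pcoa(D, k = 2)
  expect_equal(em$eigenvalues[1], em$eigenvalues[2], tolerance = 1e-10)
  expect_true(all(em$eigenvalues > 0))
  expect_equal(sum(em$pct_variance), 100, tolerance = 1e-8)
})

test_that("t-SNE is seed-deterministic and validates perplexity", {
  sim <- generate_gradient(n = 35, p = 60, mode = "counts", seed = 62)
  D <- jaccard_matrix(sim$X)
  e1 <- tsne_embed(D, k = 2, seed = 3, perplexity = 8, max_iter = 250)
  e2 <- tsne_embed(D, k = 2, seed = 3, perplexity = 8, max_iter = 250)
  expect_identical(e1$coords, e2$coords)
  expect_error(tsne_embed(D, perplexity = 12), "perplexity")
})

test_that("t-SNE arranges the synthetic gradient in latent order", {
  sim <- generate_gradient(n = 40, p = 120, mode = "counts", seed = 63)
  D <- jaccard_matrix(sim$X)
  em <- tsne_embed(D, k = 2, seed = 1, perplexity = 10)
  ## project onto the principal direction of the embedding
  pc <- prcomp(em$coords)$x[, 1]
  expect_gte(abs(cor(pc, sim$tau_true, method = "spearman")), 0.8)
})

test_that("trajectory paths order draws by tau and pick grid-nearest highlights", {
  sim <- generate_model_draw(n = 12, sigma_eps = 0.15, seed = 64)
  fit <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 60,
                               seed = 1, control = list(max_iter = 800)))
  tp <- trajectory_paths(fit, n_paths = 10, n_highlight = 12)
  expect_length(tp$paths, 10)
  for (t in 1:10)
    expect_equal(tp$paths[[t]], order(fit$tau_draws[t, ]))
  ## constant draws: every path equals the mode ordering
  fc <- fit
  fc$tau_draws <- matrix(rep(fit$tau_hat, each = 60), nrow = 60)
  colnames(fc$tau_draws) <- colnames(fit$tau_draws)
  tpc <- trajectory_paths(fc, n_paths = 5, n_highlight = 12)
  expect_true(all(vapply(tpc$paths,
                         function(p) identical(p, order(fit$tau_hat)), TRUE)))
  ## grid-nearest selection at the endpoints
  f2 <- fit
  f2$tau_hat <- setNames(c(0, 0.5, 1, rep(0.5, 9)), colnames(fit$tau_draws))
  tp2 <- trajectory_paths(f2, n_paths = 2, n_highlight = 2)
  expect_equal(tp2$mode_path, c(1L, 3L))
  expect_warning(trajectory_paths(fit, n_paths = 1000), "draws")
})

test_that("cube slices are valid, deterministic, and centered on the draw means", {
  sim <- generate_model_draw(n = 8, sigma_eps = 0.2, seed = 65)
  fit <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 2000,
                               seed = 1, control = list(max_iter = 1500)))
  cube <- dissimilarity_cube(fit, t = 40, seed = 9)
  for (s in c(1, 20, 40)) expect_valid_dissimilarity(cube[, , s])
  expect_identical(unclass(dissimilarity_cube(fit, t = 40, seed = 9)),
                   unclass(cube))
  expect_error(dissimilarity_cube(fit, t = 5000), "at most")
  ## Monte-Carlo check of the Gamma mean identity: average many slices built
  ## from a single frozen draw against that draw's latent distance matrix
  frozen <- fit
  keep <- 7
  frozen$tau_draws <- fit$tau_draws[rep(keep, 2000), ]
  frozen$scalar_draws <- fit$scalar_draws[rep(keep, 2000), ]
  big <- dissimilarity_cube(frozen, t = 2000, seed = 2)
  delta <- buds:::mean_dissimilarity_matrix(
    fit$tau_draws[keep, ], fit$scalar_draws$b[keep],
    fit$scalar_draws$rho[keep], fit$hyper)
  mc_mean <- apply(big, c(1, 2), mean)
  up <- which(upper.tri(delta))
  v <- fit$S[up] * fit$scalar_draws$sigma_eps[keep]^2
  se3 <- 3 * sqrt(v / 2000)
  expect_true(all(abs(mc_mean[up] - delta[up]) <= se3))
  ## simulate() is the same generator
  expect_identical(unclass(simulate(fit, nsim = 40, seed = 9)),
                   unclass(cube))
})

test_that("DiSTATIS matches the straight-from-definition oracle", {
  set.seed(66)
  mk <- function(x) line_dissimilarity(x)
  slices <- list(mk(c(0, 0.4, 1)), mk(c(0, 0.55, 0.9)))
  cube <- array(0, c(3, 3, 2))
  cube[, , 1] <- slices[[1]]; cube[, , 2] <- slices[[2]]
  res <- distatis(cube, k = 2)
  ora <- oracle_distatis(slices, k = 2)
  expect_equal(res$alpha, ora$alpha, tolerance = 1e-8)
  ## consensus agrees up to per-axis sign
  for (a in 1:2) {
    d1 <- res$consensus[, a]; d2 <- ora$consensus[, a]
    expect_equal(abs(sum(d1 * d2)), sqrt(sum(d1^2) * sum(d2^2)),
                 tolerance = 1e-8)
    expect_equal(sum(d1^2), sum(d2^2), tolerance = 1e-8)
  }
  ## compromise is PSD
  ev <- eigen(ora$compromise, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("identical slices give uniform weights and reduce to classical scaling", {
  P <- cbind(c(0, 0.3, 0.7, 1.2), c(0.1, 0.6, 0.2, 0.9))
  D <- as.matrix(dist(P))
  t <- 4
  cube <- array(rep(D, t), c(4, 4, t))
  res <- distatis(cube, k = 2)
  expect_equal(res$alpha, rep(1 / t, t), tolerance = 1e-9)
  expect_equal(sum(res$alpha), 1, tolerance = 1e-9)
  em <- pcoa(D, k = 2)
  ## same subspace up to sign and the 1/lambda1 normalization of the slices
  for (a in 1:2) {
    r <- res$consensus[, a] / sqrt(sum(res$consensus[, a]^2))
    p <- em$coords[, a] / sqrt(sum(em$coords[, a]^2))
    expect_equal(abs(sum(r * p)), 1, tolerance = 1e-8)
  }
  ## slice projections average to the consensus under uniform weights
  avg <- apply(res$slice_projections, c(2, 3), mean)
  expect_equal(avg, unname(res$consensus), tolerance = 1e-8)
})

test_that("density fields are normalized with nested, sensible contours", {
  sim <- generate_model_draw(n = 15, sigma_eps = 0.25, seed = 67)
  fit <- suppressWarnings(buds(sim$D, uniform_scales(sim$D), draws = 100,
                               seed = 1, control = list(max_iter = 1500)))
  cube <- dissimilarity_cube(fit, t = 30, seed = 3)
  res <- distatis(cube, k = 2)
  fld <- density_and_contours(res, selected = c("s01", "s08"))
  cell <- diff(fld$grid$x[1:2]) * diff(fld$grid$y[1:2])
  expect_equal(sum(fld$density) * cell, 1, tolerance = 0.02)
  for (id in c("s01", "s08")) {
    a50 <- contour_area(fld, id, 0.5)
    a80 <- contour_area(fld, id, 0.8)
    a95 <- contour_area(fld, id, 0.95)
    expect_lte(a50, a80 + 1e-12)
    expect_lte(a80, a95 + 1e-12)
    expect_gt(a95, 0)
  }
  expect_error(density_and_contours(distatis(cube[, , 1:5], k = 2), "s01"),
               "at least 10")
})

test_that("consensus ordering along the first axis matches the fitted ordering", {
  sim <- generate_model_draw(n = 25, sigma_eps = 0.2, seed = 68)
  fit <- buds(sim$D, uniform_scales(sim$D), draws = 100, seed = 1)
  res <- distatis(dissimilarity_cube(fit, t = 50, seed = 1), k = 2)
  expect_gte(abs(cor(res$consensus[, 1], coef(fit), method = "spearman")),
             0.9)
})
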