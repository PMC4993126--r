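# breadth-first graph distances from a seed vertex over the mesh adjacency
bfs_distances <- function(A, start) {
  D <- nrow(A)
  dist <- rep(Inf, D)
  dist[start] <- 0
  frontier <- start
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & is.infinite(dist))
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

test_that("zero smoothing gives single-vertex indicator patches", {
  sp <- tiny_space()
  b <- greens_patch_basis(sp, 10, smoothing = 0, seed = 1)
  for (p in seq_len(10)) {
    g <- b$patches[, p]
    expect_equal(g[b$seed_vertices[p]], 1, tolerance = 1e-9)
    expect_lt(max(abs(g[-b$seed_vertices[p]])), 1e-9)
  }
})

test_that("patch amplitude decays with graph distance from the seed", {
  sp <- make_cortical_surrogate(162, radii = c(70, 70, 70))  # regular mesh
  b <- greens_patch_basis(sp, 8, smoothing = 2, seed = 3)
  for (p in seq_len(8)) {
    g <- b$patches[, p]
    dist <- bfs_distances(sp$adjacency, b$seed_vertices[p])
    ring_means <- tapply(g, dist, mean)
    expect_true(all(diff(ring_means) < 0))
  }
})

test_that("a full basis puts every vertex under some patch maximum", {
  sp <- tiny_space()
  D <- nrow(sp$vertices)
  b <- greens_patch_basis(sp, D, smoothing = 1, seed = 1)
  argmaxes <- apply(b$patches, 2, which.max)
  expect_setequal(argmaxes, seq_len(D))
  expect_error(greens_patch_basis(sp, D + 1, smoothing = 1), "exceed")
})

test_that("source covariance assembly follows the exponential weighting", {
  sp <- tiny_space()
  b <- greens_patch_basis(sp, 6, smoothing = 1, seed = 2)
  g <- b$patches[, 3]
  Q1 <- assemble_source_covariance(b, 0, 3)
  expect_equal(Q1, tcrossprod(g), tolerance = 1e-12)
  # a strongly down-weighted patch contributes nothing
  Qoff <- assemble_source_covariance(b, c(0, -60), c(3, 4))
  expect_equal(Qoff, Q1, tolerance = 1e-20)
  # the same patch twice at log 2 quadruples the component
  Q4 <- assemble_source_covariance(b, c(log(2), log(2)), c(3, 3))
  expect_equal(Q4, 4 * tcrossprod(g), tolerance = 1e-12)
  expect_error(assemble_source_covariance(b, numeric(0), integer(0)),
               "non-empty")
})

test_that("free energy reproduces the closed form at the identity point", {
  Cn <- 4; Tn <- 17
  st <- list(model_cov = diag(Cn), data_cov = diag(Cn), n_temporal = Tn,
             n_spatial = Cn, prior_means = c(-1, -1),
             posterior_means = c(-1, -1), prior_cov = diag(2),
             posterior_cov = diag(2))
  expect_equal(free_energy(st), -(Tn * Cn / 2) * (1 + log(2 * pi)),
               tolerance = 1e-12)
})

test_that("accuracy terms equal the Gaussian log likelihood of the data", {
  # with point hyperpriors (eta = mu, Upsilon = Omega) the complexity
  # vanishes and F must equal sum_t log N(y_t; 0, Delta) when C is the
  # uncentred second-moment matrix of the data
  set.seed(11)
  Cn <- 3; Tn <- 40
  Y <- matrix(rnorm(Cn * Tn), Cn)
  Delta <- random_spd(Cn, seed = 12)
  Cd <- tcrossprod(Y) / Tn
  st <- list(model_cov = Delta, data_cov = Cd, n_temporal = Tn,
             n_spatial = Cn, prior_means = 0, posterior_means = 0,
             prior_cov = diag(1), posterior_cov = diag(1))
  # independent oracle: direct multivariate-normal log density per sample
  U <- chol(Delta)
  Z <- backsolve(U, Y, transpose = TRUE)
  ll <- -Tn / 2 * Cn * log(2 * pi) - Tn * sum(log(diag(U))) -
    0.5 * sum(Z^2)
  expect_equal(free_energy(st), ll, tolerance = 1e-8)
})

test_that("inflating the model covariance away from the data lowers F", {
  Cd <- random_spd(4, seed = 13)
  fe <- vapply(c(1, 1.5, 2, 4), function(c_scale) {
    st <- list(model_cov = c_scale * Cd, data_cov = Cd, n_temporal = 25,
               n_spatial = 4, prior_means = 0, posterior_means = 0,
               prior_cov = diag(1), posterior_cov = diag(1))
    free_energy(st)
  }, numeric(1))
  expect_true(all(diff(fe) < 0))
})

test_that("ReML recovers a single patch amplitude and the noise floor", {
  sp <- tiny_space()
  sens <- tiny_sensors(24)
  lf <- leadfield_sphere(sp, sens)
  b <- greens_patch_basis(sp, 12, smoothing = 1, seed = 4)
  p <- 5
  a <- lf$gain %*% b$patches[, p]
  c_true <- 3.7
  sigma2 <- 0.2 * c_true * mean(a^2)
  data_cov <- c_true * tcrossprod(a) + diag(sigma2, 24)
  st <- reml_optimize(data_cov, lf, b, active = p, n_samples = 10000)
  expect_true(all(diff(st$f_trace) >= -1e-8))
  expect_gte(st$free_energy, st$f_trace[1])
  # hyperparameters back in original data units
  c_hat <- exp(st$lambdas[1]) * st$comp_scales[1] / st$data_scale
  expect_equal(unname(c_hat), c_true, tolerance = 0.2)
  s2_hat <- exp(st$lambdas[2]) / st$data_scale
  expect_equal(unname(s2_hat), sigma2, tolerance = 0.1)
})

test_that("noise-only data drives patches to the floor and fits the
           noise variance", {
  sp <- tiny_space(); sens <- tiny_sensors(24)
  lf <- leadfield_sphere(sp, sens)
  b <- greens_patch_basis(sp, 12, smoothing = 1, seed = 4)
  sigma2 <- 2.4
  data_cov <- diag(sigma2, 24)
  st <- reml_optimize(data_cov, lf, b, active = c(2, 7), n_samples = 5000)
  s2_hat <- exp(st$lambdas[3]) / st$data_scale
  expect_equal(unname(s2_hat), sigma2, tolerance = 0.1)
  # patch contributions to the sensor covariance (exp(lambda) in the
  # trace-normalised space) stay far below the noise component
  patch_pow <- exp(st$lambdas[1:2]) / st$data_scale
  expect_lt(max(patch_pow), sigma2 / 10)
  # greedy on the same data refuses to add patches
  g <- greedy_search(data_cov, lf, b, n_samples = 5000)
  expect_equal(length(g$active_patches), 0)
  expect_true("noise-only" %in% g$flag)
})

test_that("greedy search finds simulated patches and ascends in F", {
  sp <- tiny_space(); sens <- tiny_sensors(24)
  lf <- leadfield_sphere(sp, sens)
  b <- greens_patch_basis(sp, 12, smoothing = 1, seed = 4)
  a1 <- lf$gain %*% b$patches[, 3]
  a2 <- lf$gain %*% b$patches[, 9]
  sigma2 <- 0.05 * mean(a1^2)
  data_cov <- 2 * tcrossprod(a1) + 1.5 * tcrossprod(a2) + diag(sigma2, 24)
  res <- greedy_search(data_cov, lf, b, n_samples = 5000)
  expect_true(all(diff(res$f_path) >= 0))
  expect_gte(res$free_energy, res$f_path[1])
  # the first selected patch sits on or next to a true seed
  dist3 <- bfs_distances(sp$adjacency, b$seed_vertices[3])
  dist9 <- bfs_distances(sp$adjacency, b$seed_vertices[9])
  first_seed <- b$seed_vertices[res$active_patches[1]]
  expect_lte(min(dist3[first_seed], dist9[first_seed]), 1)
  # both generating patches are represented in the active set
  sel <- b$seed_vertices[res$active_patches]
  expect_lte(min(dist3[sel]), 1)
  expect_lte(min(dist9[sel]), 1)
})

test_that("MAP estimate matches the normal-equations posterior mean", {
  # tiny fully determined system: C = 2 sensors, D = 3 sources
  L <- rbind(c(1.0, 0.4, -0.3),
             c(0.2, -0.8, 0.5))
  lf <- structure(list(gain = L, conductor = NULL), class = "lead_field")
  basis <- structure(list(patches = diag(3), seed_vertices = 1:3,
                          smoothing = 0), class = "patch_basis")
  lam <- c(0.3, -0.5, 0.1)
  lam_noise <- log(0.7)
  Q <- diag(exp(lam))
  Delta <- L %*% Q %*% t(L) + exp(lam_noise) * diag(2)
  st <- structure(list(lambdas = c(lam, lam_noise), active = 1:3,
                       comp_scales = rep(1, 3), data_scale = 1,
                       model_cov = Delta), class = "reml_state")
  set.seed(14)
  Y <- matrix(rnorm(2 * 6), 2)
  J <- map_estimate(st, lf, basis, Y)
  # oracle: (L' Qn^-1 L + Q^-1)^-1 L' Qn^-1 Y for full-rank Q
  Qn_inv <- diag(2) / exp(lam_noise)
  J_or <- solve(t(L) %*% Qn_inv %*% L + solve(Q)) %*% t(L) %*% Qn_inv %*% Y
  expect_lt(max(abs(J - J_or)) / max(abs(J_or)), 1e-10)
  # linear in Y
  expect_equal(map_estimate(st, lf, basis, 2 * Y), 2 * J, tolerance = 1e-12)
  # enormous noise suppresses the estimate
  st_inf <- st
  st_inf$model_cov <- L %*% Q %*% t(L) + 1e12 * diag(2)
  expect_lt(max(abs(map_estimate(st_inf, lf, basis, Y))), 1e-9)
  # no active patches: zero prior gives a zero estimate
  st0 <- structure(list(lambdas = 0, active = integer(0),
                        comp_scales = numeric(0), data_scale = 1,
                        model_cov = diag(2)), class = "reml_state")
  expect_true(all(map_estimate(st0, lf, basis, Y) == 0))
})
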