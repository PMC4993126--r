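# Small geometry fixtures shared across tests (built once per test run).

tiny_space <- function(radii = c(70, 85, 65)) {
  make_cortical_surrogate(42, radii = radii)
}

tiny_sensors <- function(n = 24, radius = 130) {
  make_sensor_helmet(n, radius, coverage = 0.6, seed = 1)
}

# Random symmetric positive-definite matrix
random_spd <- function(C, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(C * C), C)
  crossprod(A) + diag(0.5, C)
}

# Brute-force most probable path log-probability over all K^T paths
enumerate_best_path <- function(logPi0, logPi, logB) {
  T <- nrow(logB); K <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- logPi0[p[1]] + logB[1, p[1]]
    if (T > 1) for (t in 2:T)
      lp <- lp + logPi[p[t - 1], p[t]] + logB[t, p[t]]
    if (lp > best) best <- lp
  }
  best
}

# Path log-probability of a specific path under a meg_hmm model and data
path_logprob <- function(model, data, labels) {
  X <- t(data$Y)
  K <- model$K
  logB <- vapply(seq_len(K), function(k)
    megscan:::mvn_logdensity(X, model$means[k, ], model$covariances[[k]]),
    numeric(nrow(X)))
  lp <- log(model$initial_probs[labels[1]]) + logB[1, labels[1]]
  if (length(labels) > 1) for (t in 2:length(labels))
    lp <- lp + log(model$transition_matrix[labels[t - 1], labels[t]]) +
      logB[t, labels[t]]
  lp
}

# Hand-built meg_hmm from explicit parameters
manual_hmm <- function(means, covariances, transition, initial) {
  structure(list(K = nrow(means), means = means, covariances = covariances,
                 transition_matrix = transition, initial_probs = initial,
                 loglik = 0, converged = TRUE, projection = NULL),
            class = "meg_hmm")
}
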