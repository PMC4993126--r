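#' Gaussian-emission hidden Markov segmentation
#'
#' Sensor recordings whose second-order statistics switch between a small
#' number of regimes are segmented by a K-state HMM whose observation model
#' for state k is a multivariate normal with its own mean and full
#' covariance.  Fitting is maximum-likelihood Baum-Welch EM with k-means
#' initialisation and multiple restarts; decoding is Viterbi (the jointly
#' most probable path).
#'
#' @name megscan-hmm
NULL

#' Choose the number of states from the singular-value elbow
#'
#' Computes the singular values of the data covariance Y Y' and returns the
#' index at which the log-spectrum has its sharpest convex kink (the
#' maximiser i of log s_i - 2 log s_{i+1} + log s_{i+2}), capped at
#' \code{cap}.  With fewer than three numerically nonzero singular values
#' the rank itself (capped) is returned.
#'
#' @param data a \code{sensor_data}.
#' @param cap upper bound on the returned state count (default 10).
#' @return integer state count.
#' @export
select_num_states <- function(data, cap = 10L) {
  stopifnot(inherits(data, "sensor_data"))
  if (cap < 1) stop("cap must be >= 1")
  M <- tcrossprod(data$Y)
  s <- eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values
  s <- s[s > max(s) * 1e-12]
  if (length(s) == 0) stop("degenerate (rank-0) data")
  if (length(s) < 3) return(min(length(s), as.integer(cap)))
  ls <- log(s)
  m <- length(ls)
  d2 <- ls[1:(m - 2)] - 2 * ls[2:(m - 1)] + ls[3:m]
  as.integer(min(which.max(d2), cap))
}

# log N(x; mu, Sigma) for all rows of X (T x C), via Cholesky
mvn_logdensity <- function(X, mu, Sigma) {
  C <- ncol(X)
  U <- chol(sym(Sigma))
  Z <- sweep(X, 2, mu, "-") %*% backsolve(U, diag(C))
  -0.5 * (C * log(2 * pi) + 2 * sum(log(diag(U))) + rowSums(Z^2))
}

regularize_cov <- function(S, eps = 1e-6) {
  C <- nrow(S)
  sym(S) + diag(eps * sum(diag(S)) / C + 1e-300, C)
}

#' Fit a Gaussian-emission HMM by EM
#'
#' Baum-Welch expectation-maximisation with full state covariances,
#' k-means initialisation and \code{n_restarts} independent restarts; the
#' restart with the highest final log-likelihood is returned.  State
#' covariances are ridge-regularised by eps * tr(Sigma)/C on the diagonal
#' (eps = 1e-6).
#'
#' @param data a \code{sensor_data} (channels x samples).
#' @param K number of states.
#' @param seed integer seed controlling initialisation.
#' @param n_restarts independent EM restarts (default 5).
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence threshold on the per-sample log-likelihood
#'   improvement.
#' @param n_pca optional dimensionality reduction: fit the chain on the
#'   projections onto this many leading principal components of the data
#'   covariance (the standard practice for high-density sensor arrays,
#'   where full-rank state covariances are noisy to estimate).  The
#'   projection is stored in the model and re-applied by \code{viterbi}.
#'   NULL (default) fits in full sensor space.
#' @return an object of class \code{meg_hmm} with fields \code{K},
#'   \code{means} (K x C), \code{covariances} (list of C x C),
#'   \code{transition_matrix}, \code{initial_probs}, \code{loglik}
#'   (trace of the best restart) and \code{converged}.
#' @export
fit_hmm <- function(data, K, seed = 1L, n_restarts = 5L, max_iter = 100L,
                    tol = 1e-4, n_pca = NULL) {
  stopifnot(inherits(data, "sensor_data"))
  X <- t(data$Y)
  T <- nrow(X); C <- ncol(X)
  if (K < 1) stop("K must be >= 1")
  if (T <= K) stop("need more samples than states")
  projection <- NULL
  if (!is.null(n_pca) && n_pca < C) {
    projection <- eigen(sym(stats::cov(X)),
                        symmetric = TRUE)$vectors[, seq_len(n_pca), drop = FALSE]
    X <- X %*% projection
  }
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seeds[r],
                     baum_welch(X, K, max_iter = max_iter, tol = tol))
    if (is.null(best) || utils::tail(fit$loglik, 1) > utils::tail(best$loglik, 1))
      best <- fit
  }
  structure(c(best, list(projection = projection,
                         channel_names = data$channel_names, seed = seed)),
            class = "meg_hmm")
}

baum_welch <- function(X, K, max_iter, tol) {
  T <- nrow(X); C <- ncol(X)
  # --- initialisation: k-means on windowed second-moment features.
  # Emissions are near zero-mean and differ mainly in covariance, so raw
  # samples carry no stable cluster structure (signs are symmetric).
  # Instead each sample is described by the local second moments of its
  # leading principal-component projections, averaged over a short moving
  # window -- a sliding covariance signature -- and those signatures are
  # clustered.
  if (K == 1) {
    z <- rep(1L, T)
  } else {
    m <- min(C, K + 1)
    pc <- eigen(sym(stats::cov(X)), symmetric = TRUE)$vectors[, seq_len(m)]
    P <- X %*% pc
    P <- sweep(P, 2, pmax(apply(P, 2, stats::sd), 1e-300), "/")
    w <- min(8L, max(1L, T %/% (4L * K)))
    kern <- rep(1 / w, w)
    ij <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
    feat <- vapply(seq_len(nrow(ij)), function(r) {
      f <- P[, ij[r, 1]] * P[, ij[r, 2]]
      if (w > 1) {
        g <- stats::filter(f, kern, sides = 2)
        f[!is.na(g)] <- g[!is.na(g)]
      }
      f
    }, numeric(T))
    feat <- scale(feat)
    feat[!is.finite(feat)] <- 0
    km <- suppressWarnings(stats::kmeans(feat, centers = K, nstart = 5,
                                         iter.max = 50))
    z <- km$cluster
  }
  means <- matrix(0, K, C)
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(z == k)
    if (length(idx) < 2) idx <- sample.int(T, max(2, T %/% K))
    means[k, ] <- colMeans(X[idx, , drop = FALSE])
    covs[[k]] <- regularize_cov(stats::cov(X[idx, , drop = FALSE]))
  }
  # diagonally dominant start encourages persistent states
  Pi <- matrix(0.2 / max(1, K - 1), K, K)
  diag(Pi) <- if (K > 1) 0.8 else 1
  pi0 <- rep(1 / K, K)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logB <- vapply(seq_len(K),
                   function(k) mvn_logdensity(X, means[k, ], covs[[k]]),
                   numeric(T))
    shift <- apply(logB, 1, max)
    B <- exp(logB - shift)
    # --- scaled forward-backward
    alpha <- matrix(0, T, K)
    cvec <- numeric(T)
    a <- pi0 * B[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:T) {
      a <- (alpha[t - 1, ] %*% Pi) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
    beta <- matrix(0, T, K)
    beta[T, ] <- 1
    for (t in (T - 1):1)
      beta[t, ] <- (Pi %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    ll <- sum(log(cvec)) + sum(shift)
    loglik <- c(loglik, ll)
    if (length(loglik) > 1 &&
        (ll - loglik[length(loglik) - 1]) < tol * T &&
        ll >= loglik[length(loglik) - 1]) {
      converged <- TRUE
      break
    }
    # --- transition counts
    xi <- matrix(0, K, K)
    for (t in 2:T)
      xi <- xi + outer(alpha[t - 1, ], B[t, ] * beta[t, ] / cvec[t]) * Pi
    # --- M-step
    pi0 <- gamma[1, ]
    Pi <- xi / pmax(rowSums(xi), 1e-300)
    Ng <- colSums(gamma)
    for (k in seq_len(K)) {
      w <- gamma[, k]
      if (Ng[k] < 1e-8) next  # starved state: keep previous parameters
      means[k, ] <- colSums(X * w) / Ng[k]
      Xc <- sweep(X, 2, means[k, ], "-") * sqrt(w)
      covs[[k]] <- regularize_cov(crossprod(Xc) / Ng[k])
    }
  }
  list(K = K, means = means, covariances = covs, transition_matrix = Pi,
       initial_probs = pi0, loglik = loglik, converged = converged)
}

#' @export
print.meg_hmm <- function(x, ...) {
  cat(sprintf("<meg_hmm> K = %d states, %d channels, loglik %.1f (%s)\n",
              x$K, length(x$channel_names), utils::tail(x$loglik, 1),
              if (x$converged) "converged" else "max-iter"))
  invisible(x)
}

#' Viterbi decoding of the most probable state path
#'
#' Max-product dynamic programming in log space; ties are broken towards
#' the lowest state index.
#'
#' @param model a \code{meg_hmm}.
#' @param data a \code{sensor_data} with matching channel dimension.
#' @return a \code{state_sequence}.
#' @export
viterbi <- function(model, data) {
  stopifnot(inherits(model, "meg_hmm"), inherits(data, "sensor_data"))
  X <- t(data$Y)
  if (!is.null(model$projection)) {
    if (nrow(model$projection) != ncol(X))
      stop("model channel dimension does not match data")
    X <- X %*% model$projection
  }
  if (ncol(X) != ncol(model$means))
    stop("model channel dimension does not match data")
  K <- model$K
  T <- nrow(X)
  for (k in seq_len(K))
    if (inherits(try(chol(sym(model$covariances[[k]])), silent = TRUE), "try-error"))
      stop("singular state covariance; regularize upstream")
  logB <- vapply(seq_len(K),
                 function(k) mvn_logdensity(X, model$means[k, ],
                                            model$covariances[[k]]),
                 numeric(T))
  logPi <- log(model$transition_matrix)
  delta <- log(model$initial_probs) + logB[1, ]
  back <- matrix(0L, T, K)
  for (t in 2:T) {
    M <- delta + logPi                       # M[i, j] = delta_i + logPi[i -> j]
    back[t, ] <- max.col(t(M), ties.method = "first")
    delta <- M[cbind(back[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(T)
  path[T] <- which.max(delta)                # first maximum = lowest index
  if (T > 1) for (t in T:2) path[t - 1] <- back[t, path[t]]
  state_sequence(path, K)
}

#' Match decoded states to ground-truth states
#'
#' Builds the binary indicator time course of every true and decoded state
#' and greedily pairs them one-to-one by descending Pearson correlation.
#' A state that is never (or always) active has an undefined correlation
#' and is flagged with NA.
#'
#' @param truth,decoded \code{state_sequence}s of equal length.
#' @return an object of class \code{state_match}: a data.frame with
#'   columns \code{truth}, \code{decoded}, \code{correlation}, plus
#'   attribute \code{mean_correlation} (mean over defined matches).
#' @export
match_states <- function(truth, decoded) {
  stopifnot(inherits(truth, "state_sequence"), inherits(decoded, "state_sequence"))
  if (length(truth$labels) != length(decoded$labels))
    stop("sequences must have equal length")
  ind <- function(s) vapply(seq_len(s$K), function(k) as.numeric(s$labels == k),
                            numeric(length(s$labels)))
  A <- ind(truth); B <- ind(decoded)
  cc <- suppressWarnings(stats::cor(A, B))   # K_truth x K_decoded, NA if constant
  n <- min(truth$K, decoded$K)
  work <- cc
  pairs <- data.frame(truth = integer(0), decoded = integer(0),
                      correlation = numeric(0))
  for (i in seq_len(n)) {
    if (all(is.na(work))) break
    best <- which(work == max(work, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(truth = best[1], decoded = best[2],
                                     correlation = work[best[1], best[2]]))
    work[best[1], ] <- NA
    work[, best[2]] <- NA
  }
  # truth states left unmatched (constant indicators) are reported as NA
  left <- setdiff(seq_len(truth$K), pairs$truth)
  if (length(left))
    pairs <- rbind(pairs, data.frame(truth = left, decoded = NA,
                                     correlation = NA))
  pairs <- pairs[order(pairs$truth), ]
  rownames(pairs) <- NULL
  structure(pairs, class = c("state_match", "data.frame"),
            mean_correlation = mean(pairs$correlation, na.rm = TRUE))
}

#' Mean matched indicator correlation
#' @param match a \code{state_match}.
#' @export
mean_correlation <- function(match) attr(match, "mean_correlation")
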