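#' Segment covariance estimation
#'
#' The inversion consumes one data covariance matrix per quasi-stationary
#' segment.  Segments come from one of three partitions of the record: the
#' decoded HMM states, uniform short-time windows, or a single stationary
#' block (the average of the window covariances).
#'
#' @name megscan-segments
NULL

#' Per-segment sample covariances
#'
#' For every state k visited at least twice, pools the samples where the
#' label equals k, subtracts that segment's own mean and normalises by
#' (T_k - 1).  States with fewer than two samples are dropped and flagged.
#'
#' @param data a \code{sensor_data}.
#' @param states a \code{state_sequence} of length T.
#' @param scheme partition label: "hmm", "short_time" or "stationary".
#' @return an object of class \code{cov_set}: \code{covariances} (named
#'   list of C x C matrices), \code{counts} (samples per segment),
#'   \code{means}, \code{scheme}, and attribute \code{dropped} listing any
#'   omitted states.
#' @export
state_covariances <- function(data, states, scheme = "hmm") {
  stopifnot(inherits(data, "sensor_data"), inherits(states, "state_sequence"))
  if (length(states$labels) != ncol(data$Y))
    stop("label length must equal the number of samples")
  scheme <- match.arg(scheme, c("hmm", "short_time", "stationary"))
  X <- t(data$Y)
  covs <- list(); counts <- integer(0); means <- list()
  dropped <- integer(0)
  for (k in seq_len(states$K)) {
    idx <- which(states$labels == k)
    if (length(idx) < 2) {
      dropped <- c(dropped, k)
      next
    }
    Xk <- X[idx, , drop = FALSE]
    mk <- colMeans(Xk)
    covs[[as.character(k)]] <- sym(stats::cov(Xk))
    means[[as.character(k)]] <- mk
    counts <- c(counts, stats::setNames(length(idx), as.character(k)))
  }
  if (length(dropped))
    warning(sprintf("states with < 2 samples dropped: %s",
                    paste(dropped, collapse = ", ")))
  structure(list(covariances = covs, counts = counts, means = means,
                 scheme = scheme),
            class = "cov_set", dropped = dropped)
}

#' @export
print.cov_set <- function(x, ...) {
  cat(sprintf("<cov_set> scheme = %s, %d segments (T_k: %s)\n",
              x$scheme, length(x$covariances),
              paste(x$counts, collapse = ", ")))
  invisible(x)
}

#' Uniform short-time window labels
#'
#' Assigns successive blocks of floor(T/K) samples to windows 1..K; any
#' remainder is appended to the final window.
#'
#' @param n_samples total samples T.
#' @param K number of windows.
#' @return a \code{state_sequence} of window labels.
#' @export
window_segments <- function(n_samples, K) {
  if (K < 1) stop("K must be >= 1")
  if (K > n_samples) stop("cannot make more windows than samples")
  p <- n_samples %/% K
  labels <- rep(seq_len(K), each = p)
  if (length(labels) < n_samples)
    labels <- c(labels, rep(K, n_samples - length(labels)))
  state_sequence(labels, K)
}

#' Average the window covariances into a single stationary estimate
#'
#' @param set a \code{cov_set} with at least one covariance.
#' @return a single-segment \code{cov_set} with scheme "stationary"; its
#'   count is the total sample count of the input segments.
#' @export
pooled_covariance <- function(set) {
  stopifnot(inherits(set, "cov_set"))
  if (length(set$covariances) == 0) stop("empty covariance set")
  S <- Reduce(`+`, set$covariances) / length(set$covariances)
  structure(list(covariances = list(pooled = S),
                 counts = stats::setNames(sum(set$counts), "pooled"),
                 means = list(pooled = Reduce(`+`, set$means) / length(set$means)),
                 scheme = "stationary"),
            class = "cov_set", dropped = integer(0))
}

#' Symmetrised Kullback-Leibler divergence between covariances
#'
#' 0.5 tr(Sj^-1 Sk) + 0.5 tr(Sk^-1 Sj) - C for C x C symmetric
#' positive-definite inputs; zero iff the inputs are equal, symmetric in
#' its arguments.  Larger values indicate more dissimilar second-order
#' structure between two zero-mean Gaussian regimes.
#'
#' @param S_k,S_j symmetric positive-definite matrices of equal dimension.
#' @return non-negative scalar.
#' @export
symmetrised_kl <- function(S_k, S_j) {
  if (!all(dim(S_k) == dim(S_j))) stop("dimension mismatch")
  C <- nrow(S_k)
  tr1 <- tryCatch(sum(diag(solve(S_j, S_k))), error = function(e)
    stop("singular covariance input"))
  tr2 <- tryCatch(sum(diag(solve(S_k, S_j))), error = function(e)
    stop("singular covariance input"))
  0.5 * tr1 + 0.5 * tr2 - C
}

#' Pairwise symmetrised-KL matrix of a covariance set
#'
#' @param set a \code{cov_set}.
#' @return symmetric matrix of pairwise divergences.
#' @export
skl_matrix <- function(set) {
  stopifnot(inherits(set, "cov_set"))
  n <- length(set$covariances)
  M <- matrix(0, n, n, dimnames = list(names(set$covariances),
                                       names(set$covariances)))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <-
        symmetrised_kl(set$covariances[[i]], set$covariances[[j]])
    }
  M
}
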