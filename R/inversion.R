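#' Parametric empirical Bayes source inversion
#'
#' The source covariance is modelled as a weighted sum of smooth cortical
#' patch components, Q = sum_p exp(lambda_p) Q_p, plus white sensor noise
#' exp(lambda_noise) I.  The log-scale hyperparameters are optimised by
#' restricted maximum likelihood (ReML) ascent on the variational free
#' energy, patches are admitted by a greedy forward search, and the final
#' free energy scores the head model that produced the lead field.
#'
#' @name megscan-inversion
NULL

# Even surface coverage: greedily add the vertex farthest from the chosen
# set (Euclidean), starting from `start`.
farthest_point_seeds <- function(vertices, n, start = 1L) {
  D <- nrow(vertices)
  sel <- integer(n)
  sel[1] <- start
  mind <- colSums((t(vertices) - vertices[start, ])^2)
  if (n > 1) for (i in 2:n) {
    nxt <- which.max(mind)
    sel[i] <- nxt
    mind <- pmin(mind, colSums((t(vertices) - vertices[nxt, ])^2))
  }
  sort(sel)
}

#' Green's-function patch basis on the cortical mesh
#'
#' Patch p is the column, at a seed vertex, of the matrix exponential
#' exp(sigma * A_n) of the symmetrically normalised mesh adjacency
#' A_n = D^-1/2 A D^-1/2: a smooth bump that decays with graph distance
#' from the seed.  Seeds cover the surface uniformly: farthest-point
#' sampling in Euclidean distance, started at a vertex chosen by
#' \code{seed}, so no region of cortex is left far from every patch (an
#' uneven dictionary biases the head-position evidence towards positions
#' where the true sources happen to fall nearer a patch centre).  The
#' implied source-covariance component is the rank-one outer product
#' Q_p = g_p g_p'.
#'
#' @param space a \code{source_space}.
#' @param n_patches number of components (<= number of vertices).
#' @param smoothing Green's-function scale sigma (0 gives single-vertex
#'   indicator patches).
#' @param seed integer seed for the seed-vertex sample.
#' @return an object of class \code{patch_basis}: \code{patches} (D x P,
#'   one column per component), \code{seed_vertices}, \code{smoothing}.
#' @export
greens_patch_basis <- function(space, n_patches, smoothing = 2, seed = 1L) {
  stopifnot(inherits(space, "source_space"))
  D <- nrow(space$vertices)
  if (n_patches > D) stop("n_patches cannot exceed the number of vertices")
  if (n_patches < 1) stop("n_patches must be >= 1")
  A <- space$adjacency
  deg <- rowSums(A)
  flag <- NULL
  if (any(deg == 0)) {
    warning("mesh has isolated vertices; patch basis may not cover them")
    flag <- "disconnected"
    deg[deg == 0] <- 1
  }
  An <- A / sqrt(outer(deg, deg))
  eg <- eigen(sym(An), symmetric = TRUE)
  seeds <- if (n_patches == D) seq_len(D) else
    farthest_point_seeds(space$vertices, n_patches,
                         start = with_seed(seed, sample.int(D, 1)))
  # columns of exp(smoothing * An) at the seed vertices
  G <- eg$vectors %*% (exp(smoothing * eg$values) *
                         t(eg$vectors[seeds, , drop = FALSE]))
  structure(list(patches = G, seed_vertices = seeds, smoothing = smoothing,
                 flag = flag),
            class = "patch_basis")
}

#' @export
print.patch_basis <- function(x, ...) {
  cat(sprintf("<patch_basis> %d patches on %d vertices (sigma = %g)\n",
              ncol(x$patches), nrow(x$patches), x$smoothing))
  invisible(x)
}

#' Assemble the source covariance from weighted patch components
#'
#' Q = sum over active p of exp(lambda_p) * scale_p * g_p g_p'.
#'
#' @param basis a \code{patch_basis}.
#' @param lambdas log-scale hyperparameters, one per active patch.
#' @param active indices into the basis columns.
#' @param scales optional per-patch positive scale factors (defaults to 1);
#'   used internally to undo the trace normalisation applied during ReML.
#' @return D x D symmetric positive-semidefinite matrix.
#' @export
assemble_source_covariance <- function(basis, lambdas, active,
                                       scales = NULL) {
  stopifnot(inherits(basis, "patch_basis"))
  if (length(active) == 0) stop("active set must be non-empty")
  if (length(lambdas) != length(active))
    stop("one lambda per active patch required")
  if (any(!is.finite(lambdas))) stop("lambdas must be finite")
  if (is.null(scales)) scales <- rep(1, length(active))
  G <- basis$patches[, active, drop = FALSE]
  W <- sweep(G, 2, sqrt(exp(lambdas) * scales), "*")
  tcrossprod(W)
}

#' Sensor-noise model
#'
#' White noise on the channels with log-scale variance hyperparameter.
#' @param lambda_noise initial log variance (the ReML optimises it).
#' @export
make_noise_model <- function(lambda_noise = 0) {
  structure(list(lambda_noise = lambda_noise, structure = "identity"),
            class = "noise_model")
}

#' Variational free energy of a ReML state
#'
#' F = -T/2 tr(Delta^-1 C) - T/2 ln|Delta| - C T/2 ln 2pi
#'     - 1/2 (mu - eta)' Omega^-1 (mu - eta) + 1/2 ln|Upsilon Omega^-1|,
#' the difference between model accuracy (first three terms, the Gaussian
#' log evidence of the data under model covariance Delta) and model
#' complexity (the hyperparameter divergence terms).
#'
#' @param state a \code{reml_state} (or any list carrying
#'   \code{model_cov}, \code{data_cov}, \code{n_temporal},
#'   \code{n_spatial}, \code{prior_means}, \code{posterior_means},
#'   \code{prior_cov}, \code{posterior_cov}).
#' @return scalar free energy (nats).
#' @export
free_energy <- function(state) {
  Delta <- state$model_cov
  Cd <- state$data_cov
  Tn <- state$n_temporal
  Cn <- state$n_spatial
  U <- tryCatch(chol(sym(Delta)), error = function(e)
    stop("singular model covariance"))
  logdet <- 2 * sum(log(diag(U)))
  tr_term <- sum(diag(chol2inv(U) %*% Cd))
  acc <- -Tn / 2 * tr_term - Tn / 2 * logdet - Cn * Tn / 2 * log(2 * pi)
  d <- state$prior_means - state$posterior_means
  Om <- state$prior_cov
  Up <- state$posterior_cov
  cmplx <- -0.5 * sum(d * solve(Om, d)) +
    0.5 * (determinant(Up, logarithm = TRUE)$modulus -
             determinant(Om, logarithm = TRUE)$modulus)
  as.numeric(acc + cmplx)
}

# Internal: full objective at lambda for the scaled rank-one component model.
# Atil: C x k scaled sensor signatures (may have 0 columns); last lambda is
# the noise component.  Returns F and the quantities the gradient reuses.
reml_objective <- function(lambda, Atil, Chat, Tn, mu, om_inv, log_det_om) {
  Cn <- nrow(Chat)
  k <- ncol(Atil)
  e <- exp(lambda)
  Delta <- diag(e[k + 1], Cn)
  if (k > 0)
    Delta <- Delta + tcrossprod(sweep(Atil, 2, sqrt(e[seq_len(k)]), "*"))
  U <- tryCatch(chol(sym(Delta)), error = function(e2) NULL)
  ridge <- 0
  while (is.null(U) && ridge < 6) {
    ridge <- ridge + 1
    Delta <- Delta + diag(10^(-8 + ridge) * sum(diag(Delta)) / Cn, Cn)
    U <- tryCatch(chol(sym(Delta)), error = function(e2) NULL)
  }
  if (is.null(U)) return(NULL)
  P <- chol2inv(U)
  PC <- P %*% Chat
  # gradient pieces
  if (k > 0) {
    Ue <- P %*% Atil                       # C x k, columns P a_i
    trPA <- colSums(Atil * Ue)             # tr(P A_i)
    trPAPC <- colSums(Ue * (Chat %*% Ue))  # tr(P A_i P C)
  } else {
    Ue <- matrix(0, Cn, 0); trPA <- numeric(0); trPAPC <- numeric(0)
  }
  trP <- sum(diag(P))
  trPPC <- sum(P * t(PC))
  g_acc <- Tn / 2 * e * c(trPAPC, trPPC) - Tn / 2 * e * c(trPA, trP)
  grad <- g_acc - om_inv * (lambda - mu)
  # expected curvature (Fisher) of the accuracy part + prior precision
  H <- matrix(0, k + 1, k + 1)
  if (k > 0) {
    S <- crossprod(Atil, Ue)               # a_i' P a_j
    H[seq_len(k), seq_len(k)] <- S^2
    H[seq_len(k), k + 1] <- H[k + 1, seq_len(k)] <- colSums(Ue^2)
  }
  H[k + 1, k + 1] <- sum(P^2)
  H <- Tn / 2 * (e %o% e) * H + diag(om_inv, k + 1)
  Ups <- tryCatch(solve(H), error = function(e2) NULL)
  if (is.null(Ups)) Ups <- solve(H + diag(1e-8, k + 1))
  logdet <- 2 * sum(log(diag(U)))
  Fv <- -Tn / 2 * sum(diag(PC)) - Tn / 2 * logdet -
    Cn * Tn / 2 * log(2 * pi) -
    0.5 * sum(om_inv * (lambda - mu)^2) +
    0.5 * (determinant(Ups, logarithm = TRUE)$modulus - log_det_om)
  list(F = as.numeric(Fv), grad = grad, H = H, Ups = Ups, Delta = Delta,
       P = P)
}

#' ReML hyperparameter optimisation
#'
#' Fisher-scoring ascent on the free energy over the log-scale
#' hyperparameters of the active patch components plus the sensor-noise
#' component, with backtracking to keep the trajectory non-decreasing.
#' The data covariance is pre-scaled to tr(C) = C and each patch's sensor
#' component to the same trace, so hyperparameters are comparable across
#' patches; the scales are recorded and undone by \code{map_estimate}.
#'
#' @param data_cov C x C segment covariance (symmetric PSD).
#' @param leadfield a \code{lead_field}.
#' @param basis a \code{patch_basis}.
#' @param active indices of the active patches (may be empty for a
#'   noise-only model).
#' @param noise a \code{noise_model} (initial noise log-variance).
#' @param priors list with scalar \code{mu} (prior mean of every
#'   hyperparameter) and \code{omega} (prior variance); defaults mu = -8,
#'   omega = 16 give a weak log-scale shrinkage prior.
#' @param n_samples number of samples behind \code{data_cov} (the T of the
#'   free energy).
#' @param max_iter,tol iteration cap and convergence threshold (nats); the
#'   fit is converged when the improvement stays below \code{tol} for 4
#'   successive iterations.
#' @param lambda_init optional warm-start vector (patches then noise).
#' @return an object of class \code{reml_state}; fields include
#'   \code{lambdas} (named, patches then "noise"), \code{free_energy},
#'   \code{f_trace}, \code{model_cov}, \code{data_cov} (both in the scaled
#'   space), \code{posterior_cov}, \code{comp_scales}, \code{data_scale},
#'   \code{converged}.
#' @export
reml_optimize <- function(data_cov, leadfield, basis, active = integer(0),
                          noise = make_noise_model(),
                          priors = list(mu = -8, omega = 16),
                          n_samples, max_iter = 128L, tol = 1e-2,
                          lambda_init = NULL) {
  stopifnot(inherits(leadfield, "lead_field"), inherits(basis, "patch_basis"))
  Cn <- nrow(data_cov)
  if (n_samples < 2) stop("need at least 2 samples behind the covariance")
  trC <- sum(diag(data_cov))
  if (trC <= 0) stop("data covariance must have positive trace")
  sC <- Cn / trC
  Chat <- sym(data_cov) * sC
  k <- length(active)
  if (k > 0) {
    Asig <- leadfield$gain %*% basis$patches[, active, drop = FALSE]
    csum <- colSums(Asig^2)
    if (any(csum <= 0)) stop("patch with zero sensor signature")
    comp_scales <- Cn / csum
    Atil <- sweep(Asig, 2, sqrt(comp_scales), "*")
  } else {
    Atil <- matrix(0, Cn, 0)
    comp_scales <- numeric(0)
  }
  mu <- priors$mu
  om <- priors$omega
  om_inv <- 1 / om
  log_det_om <- (k + 1) * log(om)
  lambda <- if (!is.null(lambda_init)) lambda_init else
    c(rep(mu, k), noise$lambda_noise)
  if (length(lambda) != k + 1) stop("lambda_init has the wrong length")
  obj <- reml_objective(lambda, Atil, Chat, n_samples, mu, om_inv, log_det_om)
  if (is.null(obj)) stop("model covariance irreparably singular")
  f_trace <- obj$F
  flag <- NULL
  stall <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dl <- tryCatch(solve(obj$H, obj$grad), error = function(e)
      solve(obj$H + diag(1e-6, k + 1), obj$grad))
    mx <- max(abs(dl))
    if (mx > 4) dl <- dl * (4 / mx)       # clamp overshoot of the log step
    step <- 1
    new_obj <- NULL
    for (half in 0:11) {
      cand <- reml_objective(lambda + step * dl, Atil, Chat, n_samples,
                             mu, om_inv, log_det_om)
      if (!is.null(cand) && cand$F >= obj$F - 1e-9) {
        new_obj <- cand
        break
      }
      step <- step / 2
    }
    if (is.null(new_obj)) break           # no ascent step found
    lambda <- lambda + step * dl
    dF <- new_obj$F - obj$F
    obj <- new_obj
    f_trace <- c(f_trace, obj$F)
    stall <- if (dF < tol) stall + 1L else 0L
    if (stall >= 4L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) flag <- c(flag, "max-iter")
  names(lambda) <- c(if (k > 0) paste0("patch", active), "noise")
  structure(list(
    lambdas = lambda,
    prior_means = rep(mu, k + 1),
    prior_cov = diag(om, k + 1),
    posterior_means = lambda,
    posterior_cov = obj$Ups,
    model_cov = obj$Delta,
    data_cov = Chat,
    n_temporal = n_samples,
    n_spatial = Cn,
    free_energy = obj$F,
    f_trace = f_trace,
    active = active,
    comp_scales = comp_scales,
    data_scale = sC,
    converged = converged,
    flag = flag
  ), class = "reml_state")
}

#' @export
print.reml_state <- function(x, ...) {
  cat(sprintf("<reml_state> %d patches + noise, F = %.2f (%s)\n",
              length(x$active), x$free_energy,
              if (x$converged) "converged" else "max-iter"))
  invisible(x)
}

#' Control parameters for the greedy patch search
#'
#' @param max_patches cap on the active set size.
#' @param top_m candidates evaluated per step (ranked by the projection of
#'   each patch's sensor signature onto the residual data covariance).
#' @param f_stop stop when the best free-energy gain falls below this
#'   (nats).
#' @param reml_max_iter,reml_tol ReML settings for the accepted refits.
#' @param candidate_max_iter shorter ReML cap used while scoring
#'   candidates.
#' @export
greedy_control <- function(max_patches = 32L, top_m = 16L, f_stop = 1 / 32,
                           reml_max_iter = 128L, reml_tol = 1e-2,
                           candidate_max_iter = 32L) {
  list(max_patches = max_patches, top_m = top_m, f_stop = f_stop,
       reml_max_iter = reml_max_iter, reml_tol = reml_tol,
       candidate_max_iter = candidate_max_iter)
}

#' Greedy forward search over patch components
#'
#' Starts from the noise-only model and iteratively adds the patch whose
#' admission raises the free energy most, evaluating the \code{top_m}
#' candidates best aligned with the residual data covariance at each step;
#' stops when the best gain drops below \code{f_stop} or \code{max_patches}
#' is reached.
#'
#' @param data_cov C x C segment covariance.
#' @param leadfield a \code{lead_field}.
#' @param basis a \code{patch_basis}.
#' @param noise a \code{noise_model}.
#' @param n_samples samples behind the covariance.
#' @param control a \code{greedy_control} list.
#' @param priors hyperprior list passed to \code{reml_optimize}.
#' @return an object of class \code{inversion_result}: \code{free_energy},
#'   \code{lambdas}, \code{active_patches}, \code{state} (final
#'   \code{reml_state}), \code{f_path} (accepted free energies, starting
#'   at the noise-only model) and \code{flag}.
#' @export
greedy_search <- function(data_cov, leadfield, basis,
                          noise = make_noise_model(), n_samples,
                          control = greedy_control(),
                          priors = list(mu = -8, omega = 16)) {
  Cn <- nrow(data_cov)
  P <- ncol(basis$patches)
  sC <- Cn / sum(diag(data_cov))
  Chat <- sym(data_cov) * sC
  Asig <- leadfield$gain %*% basis$patches
  csum <- colSums(Asig^2)
  ok <- csum > max(csum) * 1e-14
  Atil_all <- sweep(Asig, 2, sqrt(ifelse(ok, Cn / csum, 0)), "*")
  cur <- reml_optimize(data_cov, leadfield, basis, integer(0), noise,
                       priors, n_samples, control$reml_max_iter,
                       control$reml_tol)
  f_path <- cur$free_energy
  active <- integer(0)
  flag <- NULL
  repeat {
    if (length(active) >= control$max_patches) break
    R <- Chat - cur$model_cov
    score <- colSums(Atil_all * (R %*% Atil_all))
    score[active] <- -Inf
    score[!ok] <- -Inf
    cand <- order(score, decreasing = TRUE)[seq_len(min(control$top_m,
                                                        P - length(active)))]
    cand <- cand[is.finite(score[cand])]
    if (length(cand) == 0) break
    best <- NULL
    best_idx <- NA_integer_
    warm <- cur$lambdas
    for (p in cand) {
      init <- c(warm[seq_along(active)], priors$mu,
                warm[length(warm)])
      st <- tryCatch(
        reml_optimize(data_cov, leadfield, basis, c(active, p), noise,
                      priors, n_samples, control$candidate_max_iter,
                      control$reml_tol, lambda_init = init),
        error = function(e) NULL)
      if (!is.null(st) && (is.null(best) || st$free_energy > best$free_energy)) {
        best <- st
        best_idx <- p
      }
    }
    if (is.null(best) || best$free_energy - cur$free_energy < control$f_stop) {
      if (length(active) == 0) flag <- c(flag, "noise-only")
      break
    }
    active <- c(active, best_idx)
    cur <- reml_optimize(data_cov, leadfield, basis, active, noise, priors,
                         n_samples, control$reml_max_iter, control$reml_tol,
                         lambda_init = best$lambdas)
    if (cur$free_energy < best$free_energy) cur <- best
    f_path <- c(f_path, cur$free_energy)
  }
  structure(list(
    free_energy = cur$free_energy,
    lambdas = cur$lambdas,
    active_patches = active,
    state = cur,
    f_path = f_path,
    flag = flag
  ), class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result> F = %.2f, %d active patches%s\n",
              x$free_energy, length(x$active_patches),
              if (length(x$flag)) paste0(" [", paste(x$flag, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Maximum a posteriori source estimate
#'
#' J_hat = Q L' (Q_noise + L Q L')^-1 Y with the source covariance Q
#' assembled from the state's hyperparameters (the internal trace
#' normalisation cancels, leaving the estimate in the units of Y per unit
#' lead-field gain).
#'
#' @param state a \code{reml_state} or \code{inversion_result}.
#' @param leadfield the \code{lead_field} the state was fitted with.
#' @param basis the \code{patch_basis} the state was fitted with.
#' @param data a \code{sensor_data} (or C x T matrix).
#' @return D x T matrix of source amplitude estimates.
#' @export
map_estimate <- function(state, leadfield, basis, data) {
  if (inherits(state, "inversion_result")) state <- state$state
  stopifnot(inherits(state, "reml_state"))
  Y <- if (inherits(data, "sensor_data")) data$Y else as.matrix(data)
  if (nrow(Y) != nrow(leadfield$gain)) stop("channel dimension mismatch")
  D <- ncol(leadfield$gain)
  k <- length(state$active)
  if (k == 0) return(matrix(0, D, ncol(Y)))
  lam <- state$lambdas[seq_len(k)]
  G <- basis$patches[, state$active, drop = FALSE]
  W <- sweep(G, 2, sqrt(exp(lam) * state$comp_scales), "*")   # Q_s = W W'
  U <- tryCatch(chol(sym(state$model_cov)), error = function(e)
    stop("singular model covariance"))
  # J = Q_s L' Delta^-1 Y (data scaling cancels between Q and Delta)
  W %*% crossprod(W, crossprod(leadfield$gain,
                               backsolve(U, forwardsolve(t(U), Y))))
}
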