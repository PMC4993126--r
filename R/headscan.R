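#' Head-position estimation by free-energy model comparison
#'
#' Every candidate head position implies its own lead field; inverting the
#' same data under each candidate yields a free energy (log model
#' evidence) per position and per data segment.  Summing segment free
#' energies at each position (fixed-effects aggregation) and passing the
#' totals through family-wise Bayesian model comparison yields a posterior
#' probability map over displacements whose peak is the estimated head
#' position.
#'
#' @name megscan-headscan
NULL

#' Displacement grid
#'
#' @param axes subset of c("x", "y", "z").
#' @param lo,hi,step grid range and step in mm; (hi - lo) must be an
#'   integer multiple of step.
#' @return an object of class \code{displacement_grid}: \code{axes},
#'   \code{offsets} (list per axis) and \code{positions} (n x 3 matrix,
#'   unscanned axes fixed at 0).
#' @export
build_grid <- function(axes = "x", lo = -30, hi = 30, step = 5) {
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  if (!(lo < hi) || step <= 0) stop("need lo < hi and step > 0")
  n <- (hi - lo) / step
  if (abs(n - round(n)) > 1e-9) stop("(hi - lo) must be divisible by step")
  offs <- seq(lo, hi, by = step)
  offsets <- stats::setNames(rep(list(offs), length(axes)), axes)
  grid_df <- do.call(expand.grid, offsets)
  positions <- matrix(0, nrow(grid_df), 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  for (a in axes) positions[, a] <- grid_df[[a]]
  structure(list(axes = axes, offsets = offsets, positions = positions),
            class = "displacement_grid")
}

#' @export
print.displacement_grid <- function(x, ...) {
  cat(sprintf("<displacement_grid> axes {%s}, %d positions\n",
              paste(x$axes, collapse = ", "), nrow(x$positions)))
  invisible(x)
}

#' Sweep head positions and collect segment free energies
#'
#' For every grid position the source space is displaced, the lead field
#' and the patch basis are recomputed on the displaced space (same patch
#' seed, so patch geometry follows the head), and each segment covariance
#' is inverted by the greedy search.  A failed inversion flags its row but
#' the position is retained.
#'
#' @param cov_set a \code{cov_set} of segment covariances (from
#'   \code{state_covariances} or \code{pooled_covariance}).
#' @param space the \code{source_space} at the reference (zero) position.
#' @param sensors a \code{sensor_array}.
#' @param grid a \code{displacement_grid}.
#' @param scheme label recorded in the table ("hmm_gs", "st_gs" or "gs").
#' @param n_patches,smoothing,patch_seed patch-basis settings.
#' @param control a \code{greedy_control}.
#' @param priors hyperprior list.
#' @param verbose print progress per position.
#' @return an \code{evidence_table} data.frame with columns x, y, z,
#'   scheme, segment, free_energy, n_samples, flag.
#' @export
scan_evidence <- function(cov_set, space, sensors, grid,
                          scheme = c("hmm_gs", "st_gs", "gs"),
                          n_patches = NULL, smoothing = 2, patch_seed = 1L,
                          control = greedy_control(), priors = list(mu = -8, omega = 16),
                          verbose = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cov_set, "cov_set"), inherits(grid, "displacement_grid"))
  D <- nrow(space$vertices)
  if (is.null(n_patches)) n_patches <- min(512L, max(1L, ceiling(D / 4)))
  rows <- list()
  for (i in seq_len(nrow(grid$positions))) {
    off <- grid$positions[i, ]
    sp <- displace_head(space, head_transform(off))
    lf <- leadfield_sphere(sp, sensors)
    bs <- greens_patch_basis(sp, n_patches, smoothing, seed = patch_seed)
    for (s in seq_along(cov_set$covariances)) {
      seg <- names(cov_set$covariances)[s]
      res <- tryCatch(
        greedy_search(cov_set$covariances[[s]], lf, bs,
                      n_samples = cov_set$counts[[s]],
                      control = control, priors = priors),
        error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        x = off[["x"]], y = off[["y"]], z = off[["z"]],
        scheme = scheme, segment = seg,
        free_energy = if (is.null(res)) NA_real_ else res$free_energy,
        n_samples = cov_set$counts[[s]],
        flag = if (is.null(res)) "failed" else
          paste(res$flag, collapse = ";"))
    }
    if (verbose)
      message(sprintf("position (%g, %g, %g) done", off[1], off[2], off[3]))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' Fixed-effects aggregation of segment free energies
#'
#' Per-position log evidence is the sum of that position's unflagged
#' segment free energies (segments treated as conditionally independent
#' given the head position).  Positions whose rows all failed are dropped
#' with a warning.
#'
#' @param table an \code{evidence_table}.
#' @return data.frame with columns x, y, z, scheme, log_evidence,
#'   n_segments.
#' @export
ffx_aggregate <- function(table) {
  stopifnot(is.data.frame(table))
  ok <- !is.na(table$free_energy)
  if (!any(ok)) stop("no successful inversions to aggregate")
  keys <- c("x", "y", "z", "scheme")
  agg <- stats::aggregate(free_energy ~ x + y + z + scheme, data = table[ok, ],
                          FUN = sum)
  cnt <- stats::aggregate(free_energy ~ x + y + z + scheme, data = table[ok, ],
                          FUN = length)
  names(agg)[names(agg) == "free_energy"] <- "log_evidence"
  agg$n_segments <- cnt$free_energy
  dropped <- nrow(unique(table[, keys])) - nrow(agg)
  if (dropped > 0)
    warning(sprintf("%d position(s) dropped: all segment inversions failed",
                    dropped))
  agg[order(agg$scheme, agg$x, agg$y, agg$z), , drop = FALSE]
}

#' Family-wise posterior over grouped positions
#'
#' Positions sharing a value of the grouping coordinate form one model
#' family.  Under a uniform prior over families and over models within a
#' family, the family log evidence is the log-mean evidence of its
#' members, logsumexp(F_members) - log(size); posteriors are normalised
#' across families.
#'
#' @param log_evidence data.frame from \code{ffx_aggregate} (one scheme).
#' @param by axis name(s) defining the families, e.g. "x" or
#'   c("x", "y"); families spanning all three axes give a per-position
#'   posterior.
#' @return an object of class \code{posterior_map}: a data.frame with the
#'   family coordinates and a \code{posterior} column summing to 1.
#' @export
family_posterior <- function(log_evidence, by = c("x", "y", "z")) {
  stopifnot(all(by %in% c("x", "y", "z")), length(by) >= 1)
  if (length(unique(log_evidence$scheme %||% "one")) > 1)
    stop("aggregate one scheme at a time")
  key <- interaction(log_evidence[by], drop = TRUE, lex.order = TRUE)
  fams <- split(seq_len(nrow(log_evidence)), key)
  lev <- vapply(fams, function(idx)
    logsumexp(log_evidence$log_evidence[idx]) - log(length(idx)), numeric(1))
  post <- exp(lev - logsumexp(lev))
  post <- post / sum(post)
  coords <- do.call(rbind, lapply(fams, function(idx)
    log_evidence[idx[1], by, drop = FALSE]))
  out <- cbind(coords, posterior = post)
  rownames(out) <- NULL
  out <- out[do.call(order, out[by]), , drop = FALSE]
  structure(out, class = c("posterior_map", "data.frame"), axes = by)
}

#' Marginalise a posterior map over dropped axes
#'
#' @param map a \code{posterior_map}.
#' @param keep_axes axes to keep (non-empty subset of the map's axes).
#' @return a \code{posterior_map} over the kept axes, renormalised.
#' @export
marginalize <- function(map, keep_axes) {
  axes <- attr(map, "axes")
  if (length(keep_axes) == 0 || !all(keep_axes %in% axes))
    stop("keep_axes must be a non-empty subset of the map's axes")
  key <- interaction(map[keep_axes], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(map)), key)
  post <- vapply(groups, function(idx) sum(map$posterior[idx]), numeric(1))
  coords <- do.call(rbind, lapply(groups, function(idx)
    map[idx[1], keep_axes, drop = FALSE]))
  out <- cbind(coords, posterior = post / sum(post))
  rownames(out) <- NULL
  out <- out[do.call(order, out[keep_axes]), , drop = FALSE]
  structure(out, class = c("posterior_map", "data.frame"), axes = keep_axes)
}

map_offset_norms <- function(map) {
  axes <- attr(map, "axes")
  sqrt(rowSums(as.matrix(map[, axes, drop = FALSE])^2))
}

#' Highest-posterior-density region on the grid
#'
#' The smallest set of positions, taken in descending posterior order
#' (ties broken by proximity to the grid centre), whose cumulative
#' posterior reaches \code{mass}.
#'
#' @param map a \code{posterior_map}.
#' @param mass target probability mass in (0, 1), default 0.95.
#' @return the subset of the map's rows forming the region.
#' @export
probability_mass_region <- function(map, mass = 0.95) {
  if (!(mass > 0 && mass < 1)) stop("mass must lie in (0, 1)")
  ord <- order(-map$posterior, map_offset_norms(map))
  cum <- cumsum(map$posterior[ord])
  n <- which(cum >= mass - 1e-12)[1]
  if (is.na(n)) n <- length(ord)
  out <- map[ord[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peak of a posterior map
#'
#' Argmax position; ties are broken by the smallest Euclidean offset norm,
#' then lexicographically.
#'
#' @param map a \code{posterior_map}.
#' @return named numeric vector of the peak coordinates.
#' @export
peak <- function(map) {
  if (nrow(map) == 0) stop("empty posterior map")
  axes <- attr(map, "axes")
  ord <- do.call(order, c(list(-map$posterior, map_offset_norms(map)),
                          unname(map[axes])))
  out <- as.numeric(map[ord[1], axes])
  names(out) <- axes
  out
}

#' Estimate head position from non-stationary MEG data
#'
#' The main fitting routine.  The record is segmented under one or more
#' stationarity assumptions (decoded HMM states, uniform short-time
#' windows, or a single stationary block), each segment covariance is
#' inverted with the empirical-Bayes patch scheme at every candidate head
#' displacement, and segment free energies are aggregated into a family
#' posterior over displacements per scheme.
#'
#' @param data a \code{sensor_data}.
#' @param space the reference \code{source_space}.
#' @param sensors a \code{sensor_array}.
#' @param grid a \code{displacement_grid} of candidate displacements.
#' @param schemes subset of c("hmm_gs", "st_gs", "gs").
#' @param K number of segments; NULL selects the singular-value elbow
#'   capped at 10.
#' @param hmm optionally a pre-fitted \code{meg_hmm} (used by "hmm_gs").
#' @param seed integer seed (HMM restarts, patch-seed sampling).
#' @param n_patches,smoothing patch-basis settings (default patch count
#'   min(512, D/4)).
#' @param control a \code{greedy_control}.
#' @param priors hyperprior list.
#' @param hmm_restarts,n_pca,verbose further HMM fitting options (see
#'   \code{fit_hmm}).
#' @return an object of class \code{headscan} with the evidence table,
#'   per-scheme log evidence and posterior maps, peak estimates, the
#'   fitted HMM and decoded states.  Methods: \code{print},
#'   \code{summary}, \code{coef} (peak displacement per scheme),
#'   \code{plot}.
#' @export
headscan <- function(data, space, sensors, grid = build_grid("x", -30, 30, 5),
                     schemes = c("hmm_gs", "st_gs", "gs"), K = NULL,
                     hmm = NULL, seed = 1L, n_patches = NULL, smoothing = 2,
                     control = greedy_control(), priors = list(mu = -8, omega = 16),
                     hmm_restarts = 5L, n_pca = NULL, verbose = FALSE) {
  schemes <- match.arg(schemes, c("hmm_gs", "st_gs", "gs"), several.ok = TRUE)
  if (length(schemes) == 0) stop("at least one scheme required")
  stopifnot(inherits(data, "sensor_data"))
  cl <- match.call()
  if (is.null(K)) K <- select_num_states(data, cap = 10L)
  T <- ncol(data$Y)
  states <- NULL
  cov_sets <- list()
  if ("hmm_gs" %in% schemes) {
    if (is.null(hmm)) hmm <- fit_hmm(data, K, seed = seed,
                                     n_restarts = hmm_restarts, n_pca = n_pca)
    states <- viterbi(hmm, data)
    cov_sets$hmm_gs <- state_covariances(data, states, scheme = "hmm")
  }
  if (any(c("st_gs", "gs") %in% schemes)) {
    wseg <- window_segments(T, K)
    wcov <- state_covariances(data, wseg, scheme = "short_time")
    if ("st_gs" %in% schemes) cov_sets$st_gs <- wcov
    if ("gs" %in% schemes) cov_sets$gs <- pooled_covariance(wcov)
  }
  evidence <- do.call(rbind, lapply(names(cov_sets), function(sc)
    scan_evidence(cov_sets[[sc]], space, sensors, grid, scheme = sc,
                  n_patches = n_patches, smoothing = smoothing,
                  patch_seed = seed, control = control, priors = priors,
                  verbose = verbose)))
  log_evidence <- list()
  posterior <- list()
  for (sc in names(cov_sets)) {
    le <- ffx_aggregate(evidence[evidence$scheme == sc, , drop = FALSE])
    log_evidence[[sc]] <- le
    posterior[[sc]] <- family_posterior(le, by = grid$axes)
  }
  peaks <- t(vapply(posterior, function(m) {
    p <- rep(0, 3); names(p) <- c("x", "y", "z")
    pk <- peak(m)
    p[names(pk)] <- pk
    p
  }, numeric(3)))
  structure(list(
    call = cl, K = K, grid = grid, schemes = names(cov_sets),
    evidence = evidence, log_evidence = log_evidence,
    posterior = posterior, peaks = peaks,
    hmm = hmm, states = states, cov_sets = cov_sets
  ), class = "headscan")
}

#' @export
print.headscan <- function(x, ...) {
  cat(sprintf("Head-position scan: %d positions on {%s}, K = %d segments\n",
              nrow(x$grid$positions), paste(x$grid$axes, collapse = ", "),
              x$K))
  cat("Peak displacement (mm) per scheme:\n")
  print(round(x$peaks, 2))
  invisible(x)
}

#' @export
coef.headscan <- function(object, ...) object$peaks

#' @export
summary.headscan <- function(object, mass = 0.95, ...) {
  regions <- lapply(object$posterior, probability_mass_region, mass = mass)
  out <- list(
    peaks = object$peaks,
    K = object$K,
    region_sizes = vapply(regions, nrow, integer(1)),
    regions = regions,
    mass = mass,
    n_positions = nrow(object$grid$positions),
    flags = table(object$evidence$flag[object$evidence$flag != ""])
  )
  class(out) <- "summary.headscan"
  out
}

#' @export
print.summary.headscan <- function(x, ...) {
  cat(sprintf("Head-position scan over %d positions, K = %d segments\n",
              x$n_positions, x$K))
  cat("Peak displacement (mm):\n"); print(round(x$peaks, 2))
  cat(sprintf("%.0f%% probability-mass region size (positions):\n",
              100 * x$mass))
  print(x$region_sizes)
  if (length(x$flags)) {
    cat("Flagged inversions:\n"); print(x$flags)
  }
  invisible(x)
}

#' @export
plot.headscan <- function(x, ...) {
  axes <- x$grid$axes
  if (length(axes) == 1) {
    ax <- axes[1]
    cols <- stats::setNames(seq_along(x$schemes) + 1, x$schemes)
    first <- TRUE
    for (sc in x$schemes) {
      m <- x$posterior[[sc]]
      if (first) {
        plot(m[[ax]], m$posterior, type = "b", col = cols[sc], pch = 16,
             xlab = sprintf("%s displacement (mm)", ax),
             ylab = "posterior probability",
             ylim = c(0, max(vapply(x$posterior, function(p)
               max(p$posterior), numeric(1)))), ...)
        first <- FALSE
      } else lines(m[[ax]], m$posterior, type = "b", col = cols[sc], pch = 16)
    }
    graphics::legend("topright", legend = x$schemes, col = cols, lty = 1,
                     pch = 16, bty = "n")
  } else {
    m <- marginalize(x$posterior[[1]], axes[1])
    plot(m[[axes[1]]], m$posterior, type = "b", pch = 16,
         xlab = sprintf("%s displacement (mm)", axes[1]),
         ylab = "marginal posterior", ...)
  }
  invisible(x)
}

#' Write / read an evidence table or posterior map as TSV
#' @param x data.frame to write.
#' @param path file path.
#' @export
write_evidence_table <- function(x, path) {
  utils::write.table(format_numeric_df(as.data.frame(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_table
#' @export
read_evidence_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' @rdname write_evidence_table
#' @param axes axis columns of the stored posterior map.
#' @export
read_posterior_map <- function(path, axes = NULL) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(axes)) axes <- intersect(c("x", "y", "z"), names(out))
  structure(out, class = c("posterior_map", "data.frame"), axes = axes)
}
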