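#' Synthetic non-stationary MEG data
#'
#' The study design emulated here: one stationary cortical source (left
#' primary motor cortex) active throughout the recording, plus five
#' "confound" sources gated on and off by a hidden Markov chain -- when
#' state k is active the k-th confound emits Gaussian noise at ten times
#' the stationary source's amplitude, otherwise it is silent.  The source
#' configuration is projected to the sensors through the lead field and
#' degraded with white sensor noise to a target SNR.
#'
#' @name megscan-simulator
NULL

#' MNI coordinates of the five gated confound sources
#'
#' @return 5 x 3 matrix of coordinates in mm (one row per chain state).
#' @export
confound_coordinates <- function() {
  rbind(
    c( 50, -62, 26),
    c(-50, -62, 26),
    c( 26,  32, 40),
    c(-26,  32, 40),
    c( -4,  50, 14))
}

#' Default coordinate of the stationary motor-cortex source (mm)
#' @export
stationary_coordinate <- function() c(41, -25, 49)

#' Transition matrix with a uniform between-state transition probability
#'
#' The gating chain leaves its current state with total probability
#' \code{leave} per sample, split evenly over the other states: diagonal
#' \code{1 - leave}, off-diagonal \code{leave / (K - 1)}.  The default
#' \code{leave = 0.25} gives a mean dwell time of four samples, the
#' reading of a uniform 0.25 between-state transition probability that
#' leaves states persistent enough to be visible as dwell periods.
#' \code{leave = 1} gives the memoryless extreme in which the chain moves
#' every sample (off-diagonal 0.25 exactly when K = 5).
#'
#' @param K number of states.
#' @param leave total probability of leaving the current state per sample.
#' @return K x K row-stochastic matrix.
#' @export
uniform_transition_matrix <- function(K = 5, leave = 0.25) {
  if (K == 1) return(matrix(1, 1, 1))
  if (leave < 0 || leave > 1) stop("leave must lie in [0, 1]")
  P <- matrix(leave / (K - 1), K, K)
  diag(P) <- 1 - leave
  P
}

#' Simulation configuration
#'
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param stationary_source list with \code{coord} (mm) and \code{sd}
#'   (amplitude SD, arbitrary units).
#' @param confound_sources list with \code{coords} (K x 3 mm) and \code{sd}
#'   (active-state amplitude SD).
#' @param transition_matrix K x K row-stochastic gating chain.
#' @param initial_probs initial state distribution (default uniform).
#' @param snr_db sensor-space signal-to-noise ratio in dB.
#' @param seed integer seed.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(fs = 200, duration = 75,
                              stationary_source = list(coord = stationary_coordinate(), sd = 1),
                              confound_sources = list(coords = confound_coordinates(), sd = 10),
                              transition_matrix = uniform_transition_matrix(5),
                              initial_probs = NULL,
                              snr_db = 0, seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (stationary_source$sd < 0 || any(confound_sources$sd < 0))
    stop("amplitude SDs must be non-negative")
  check_stochastic(transition_matrix)
  K <- nrow(transition_matrix)
  if (is.null(initial_probs)) initial_probs <- rep(1 / K, K)
  if (abs(sum(initial_probs) - 1) > 1e-12 || any(initial_probs < 0))
    stop("initial_probs must be a probability vector")
  structure(list(
    fs = fs, duration = duration,
    stationary_source = stationary_source,
    confound_sources = confound_sources,
    transition_matrix = transition_matrix,
    initial_probs = initial_probs,
    snr_db = snr_db, seed = as.integer(seed)
  ), class = "simulation_config")
}

check_stochastic <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("transition matrix must be square")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must be non-negative and sum to 1")
  invisible(P)
}

#' State-sequence container
#'
#' @param labels integer vector of states in 1..K.
#' @param K number of states.
#' @export
state_sequence <- function(labels, K = max(labels)) {
  labels <- as.integer(labels)
  if (length(labels) < 1 || any(labels < 1L) || any(labels > K))
    stop("labels must lie in 1..K")
  structure(list(labels = labels, K = as.integer(K)), class = "state_sequence")
}

#' Sample a Markov state sequence
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial_probs length-K initial distribution.
#' @param n_samples number of time samples.
#' @param seed integer seed.
#' @return a \code{state_sequence}.
#' @export
sample_state_sequence <- function(transition_matrix, initial_probs, n_samples,
                                  seed = 1L) {
  check_stochastic(transition_matrix)
  K <- nrow(transition_matrix)
  if (n_samples < 1) stop("n_samples must be >= 1")
  labels <- with_seed(seed, {
    s <- integer(n_samples)
    s[1] <- sample.int(K, 1, prob = initial_probs)
    if (n_samples > 1)
      for (t in 2:n_samples)
        s[t] <- sample.int(K, 1, prob = transition_matrix[s[t - 1], ])
    s
  })
  state_sequence(labels, K)
}

#' Simulate gated source time courses
#'
#' The stationary source emits unit-less Gaussian noise at its configured
#' SD for the whole record; confound source k emits at its SD exactly where
#' the gating state equals k and is zero elsewhere.
#'
#' @param config a \code{simulation_config}.
#' @param space a \code{source_space}; configured coordinates are snapped to
#'   its nearest vertices (all snaps must be distinct).
#' @param states gating \code{state_sequence} for the confounds.
#' @return an object of class \code{source_timecourses} with fields
#'   \code{J} ((1 + K) x T), \code{source_indices} and \code{truth_states}.
#' @export
simulate_sources <- function(config, space, states) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(space, "source_space"),
            inherits(states, "state_sequence"))
  coords <- rbind(config$stationary_source$coord, config$confound_sources$coords)
  idx <- snap_vertices(space, coords)
  if (anyDuplicated(idx))
    stop("two configured sources snap to the same mesh vertex; refine the mesh")
  K <- nrow(config$confound_sources$coords)
  if (states$K != K)
    stop("state sequence K does not match the number of confound sources")
  T <- length(states$labels)
  sds <- rep(config$confound_sources$sd, length.out = K)
  J <- with_seed(config$seed, {
    J <- matrix(0, K + 1, T)
    J[1, ] <- stats::rnorm(T, sd = config$stationary_source$sd)
    for (k in seq_len(K)) {
      on <- states$labels == k
      J[k + 1, on] <- stats::rnorm(sum(on), sd = sds[k])
    }
    J
  })
  structure(list(
    J = J,
    source_indices = idx,
    truth_states = states
  ), class = "source_timecourses")
}

#' Sensor-data container
#'
#' @param Y C x T matrix of sensor measurements.
#' @param fs sampling rate (Hz).
#' @param channel_names optional channel labels.
#' @export
sensor_data <- function(Y, fs, channel_names = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("need at least 2 time samples")
  if (any(!is.finite(Y))) stop("sensor data must be finite")
  structure(list(
    Y = Y, fs = fs,
    channel_names = channel_names %||% sprintf("MEG%03d", seq_len(nrow(Y)))
  ), class = "sensor_data")
}

#' @export
print.sensor_data <- function(x, ...) {
  cat(sprintf("<sensor_data> %d channels x %d samples @ %g Hz\n",
              nrow(x$Y), ncol(x$Y), x$fs))
  invisible(x)
}

#' Project source time courses to the sensors
#'
#' Noiseless sensor data Y = L J restricted to the simulated source columns.
#'
#' @param leadfield a \code{lead_field}.
#' @param sources a \code{source_timecourses}.
#' @param fs sampling rate passed through to the result (Hz).
#' @return a \code{sensor_data}.
#' @export
project_sources <- function(leadfield, sources, fs = 200) {
  stopifnot(inherits(leadfield, "lead_field"),
            inherits(sources, "source_timecourses"))
  if (max(sources$source_indices) > ncol(leadfield$gain))
    stop("source indices exceed lead-field columns")
  Y <- leadfield$gain[, sources$source_indices, drop = FALSE] %*% sources$J
  sensor_data(Y, fs, leadfield$channel_names)
}

#' Add white sensor noise at a target SNR
#'
#' i.i.d. Gaussian noise with SD equal to rms(clean) * 10^(-snr_db / 20) is
#' added to every entry, so at 0 dB the noise rms equals the signal rms.
#'
#' @param clean a \code{sensor_data} with nonzero power.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed integer seed.
#' @return a \code{sensor_data}.
#' @export
add_noise_snr <- function(clean, snr_db, seed = 1L) {
  stopifnot(inherits(clean, "sensor_data"))
  rms <- sqrt(mean(clean$Y^2))
  if (rms == 0) stop("clean signal has zero power; SNR undefined")
  sd_noise <- rms * 10^(-snr_db / 20)
  noisy <- clean
  noisy$Y <- clean$Y + with_seed(seed,
    matrix(stats::rnorm(length(clean$Y), sd = sd_noise),
           nrow(clean$Y), ncol(clean$Y)))
  noisy
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass applied to every
#' channel.
#'
#' @param data a \code{sensor_data}.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order Butterworth order of the one-pass filter (the effective
#'   attenuation is doubled by the forward-backward pass).
#' @return a filtered \code{sensor_data}.
#' @export
bandpass <- function(data, low, high, order = 4) {
  stopifnot(inherits(data, "sensor_data"))
  nyq <- data$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- data
  out$Y <- t(apply(data$Y, 1, function(ch) signal::filtfilt(bf, ch)))
  out
}

#' Simulate the full non-stationary MEG study
#'
#' End-to-end generator: builds the helmet and surrogate cortex, computes
#' the lead field, samples the gating chain and source amplitudes, projects
#' to the sensors and adds noise at the configured SNR.  All randomness is
#' derived from \code{seed}.
#'
#' @param seed master integer seed.
#' @param n_channels sensors on the helmet (default the full 274-channel
#'   whole-head system; scaled-down studies pass fewer).
#' @param n_vertices requested surrogate-mesh size.
#' @param helmet_radius helmet radius (mm).
#' @param config a \code{simulation_config}; its own seed is ignored in
#'   favour of sub-seeds derived from \code{seed}.
#' @param true_offset length-3 translation (mm) of the head used to
#'   generate the data; the returned \code{space} stays at the reference
#'   position, so a scan around the reference should recover this offset.
#' @return list with \code{data} (\code{sensor_data}), \code{sources},
#'   \code{truth_states}, \code{space}, \code{sensors}, \code{leadfield}
#'   (at the true position), \code{true_offset} and \code{config}.
#' @export
simulate_nonstationary_meg <- function(seed = 1L, n_channels = 274,
                                       n_vertices = 162, helmet_radius = 130,
                                       config = simulation_config(),
                                       true_offset = c(0, 0, 0)) {
  sub <- derive_seeds(seed, 4)
  sensors <- make_sensor_helmet(n_channels, helmet_radius, coverage = 0.6,
                                seed = sub[1])
  space <- make_cortical_surrogate(n_vertices)
  lf <- leadfield_sphere(displace_head(space, head_transform(true_offset)),
                         sensors)
  T <- round(config$fs * config$duration)
  states <- sample_state_sequence(config$transition_matrix,
                                  config$initial_probs, T, seed = sub[2])
  config$seed <- sub[3]
  src <- simulate_sources(config, space, states)
  clean <- project_sources(lf, src, fs = config$fs)
  data <- add_noise_snr(clean, config$snr_db, seed = sub[4])
  list(data = data, sources = src, truth_states = states, space = space,
       sensors = sensors, leadfield = lf,
       true_offset = as.numeric(true_offset), config = config)
}

#' Write / read sensor data as a plain-text matrix with a sidecar header
#'
#' The matrix file is tab-separated (channels in rows); header lines
#' starting with '#' carry the sampling rate and channel names.
#' @param x a \code{sensor_data}.
#' @param path file path.
#' @export
write_sensor_data <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", x$fs),
               paste0("# channels=", paste(x$channel_names, collapse = ","))),
             con)
  utils::write.table(matrix(sprintf("%.10g", x$Y), nrow(x$Y)), con,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_data
#' @export
read_sensor_data <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# fs=", "", hdr[1], fixed = TRUE))
  channels <- strsplit(sub("# channels=", "", hdr[2], fixed = TRUE), ",")[[1]]
  Y <- as.matrix(utils::read.table(path, sep = "\t", skip = 2))
  dimnames(Y) <- NULL
  sensor_data(Y, fs, channels)
}
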