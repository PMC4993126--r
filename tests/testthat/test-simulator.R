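test_that("state sequences follow the chain they are sampled from", {
  # degenerate one-state chain
  s1 <- sample_state_sequence(matrix(1, 1, 1), 1, 50, seed = 1)
  expect_equal(s1$labels, rep(1L, 50))
  # deterministic two-state flip-flop
  P <- rbind(c(0, 1), c(1, 0))
  s2 <- sample_state_sequence(P, c(1, 0), 20, seed = 2)
  expect_equal(s2$labels, rep(c(1L, 2L), 10))
  # invalid rows rejected
  expect_error(sample_state_sequence(matrix(0.3, 2, 2), c(.5, .5), 10),
               "sum to 1")
})

test_that("state occupancy matches the eigen-analysis stationary law", {
  P <- uniform_transition_matrix(5, leave = 0.25)
  # stationary distribution from the leading left eigenvector
  ev <- eigen(t(P))
  pi_stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_stat <- pi_stat / sum(pi_stat)
  expect_equal(pi_stat, rep(0.2, 5), tolerance = 1e-12)
  T <- 15000
  s <- sample_state_sequence(P, rep(0.2, 5), T, seed = 11)
  occ <- tabulate(s$labels, 5) / T
  # dwell time 1/leave inflates the variance of the occupancy estimate;
  # effective sample size ~ T * leave / (2 - leave)
  ess <- T * 0.25 / (2 - 0.25)
  se <- sqrt(0.2 * 0.8 / ess)
  expect_true(all(abs(occ - 0.2) < 3 * se))
})

test_that("sources are gated exactly by the chain state", {
  sp <- make_cortical_surrogate(162)
  cfg <- simulation_config(seed = 5)
  labels <- rep(c(1L, 2L, 4L, 5L), length.out = 400)  # state 3 never visited
  states <- state_sequence(labels, 5)
  src <- simulate_sources(cfg, sp, states)
  expect_equal(dim(src$J), c(6, 400))
  expect_true(all(src$J[4, ] == 0))            # confound 3 silent throughout
  for (k in 1:5)
    expect_true(all(src$J[k + 1, labels != k] == 0))
  expect_true(all(src$J[1, ] != 0))            # stationary source always on
})

test_that("source amplitudes meet their configured SDs", {
  sp <- make_cortical_surrogate(162)
  cfg <- simulation_config(seed = 9)
  states <- sample_state_sequence(cfg$transition_matrix, cfg$initial_probs,
                                  15000, seed = 9)
  src <- simulate_sources(cfg, sp, states)
  expect_equal(sd(src$J[1, ]), 1, tolerance = 0.05)
  for (k in 1:5) {
    on <- states$labels == k
    expect_equal(sd(src$J[k + 1, on]), 10, tolerance = 0.05)
  }
})

test_that("projection is the plain matrix product with the gain columns", {
  sp <- tiny_space(); sens <- tiny_sensors()
  lf <- leadfield_sphere(sp, sens)
  src <- structure(list(J = matrix(0, 2, 5), source_indices = c(3, 7),
                        truth_states = NULL), class = "source_timecourses")
  expect_true(all(project_sources(lf, src)$Y == 0))
  set.seed(4)
  src$J <- matrix(rnorm(10), 2, 5)
  y1 <- project_sources(lf, src)$Y
  src3 <- src; src3$J <- 3 * src$J
  expect_equal(project_sources(lf, src3)$Y, 3 * y1, tolerance = 1e-12)
  # single source, single sample: hand product
  one <- structure(list(J = matrix(2.5, 1, 2), source_indices = 7,
                        truth_states = NULL), class = "source_timecourses")
  expect_equal(project_sources(lf, one)$Y[, 1], lf$gain[, 7] * 2.5)
  bad <- src; bad$source_indices <- c(3, nrow(sp$vertices) + 5)
  expect_error(project_sources(lf, bad), "indices")
})

test_that("added noise hits the target SNR", {
  set.seed(2)
  clean <- sensor_data(matrix(rnorm(40 * 4000), 40), fs = 200)
  rms <- sqrt(mean(clean$Y^2))
  n0 <- add_noise_snr(clean, 0, seed = 1)
  expect_equal(sd(n0$Y - clean$Y), rms, tolerance = 0.02)
  # near-infinite SNR leaves the data untouched
  hi <- add_noise_snr(clean, 200, seed = 1)
  expect_equal(hi$Y, clean$Y, tolerance = 1e-8)
  # -20 dB: noise SD ten times the signal rms
  lo <- add_noise_snr(clean, -20, seed = 1)
  expect_equal(sd(lo$Y - clean$Y) / rms, 10, tolerance = 0.05)
  # power additivity within sampling error
  expect_equal(mean(n0$Y^2), mean(clean$Y^2) + rms^2, tolerance = 0.02 * rms^2)
  zero <- sensor_data(matrix(1e-300, 4, 4) * 0 + 0, fs = 10)
  zero$Y[] <- 0
  expect_error(add_noise_snr(zero, 0), "zero power")
})

test_that("identical seeds reproduce the simulation bit for bit", {
  a <- simulate_nonstationary_meg(seed = 3, n_channels = 16, n_vertices = 42)
  b <- simulate_nonstationary_meg(seed = 3, n_channels = 16, n_vertices = 42)
  expect_identical(a$data$Y, b$data$Y)
  expect_identical(a$truth_states$labels, b$truth_states$labels)
  c <- simulate_nonstationary_meg(seed = 4, n_channels = 16, n_vertices = 42)
  expect_gt(max(abs(a$data$Y - c$data$Y)), 0)
})

test_that("band-pass keeps the band and rejects the stop band", {
  fs <- 200
  t <- seq(0, 30, by = 1 / fs)
  centre <- sin(2 * pi * 21.5 * t)       # band centre of 13-30 Hz
  high <- sin(2 * pi * fs / 2.01 * t)    # near Nyquist
  x <- sensor_data(rbind(centre, high), fs)
  y <- bandpass(x, 13, 30)
  mid <- seq(1000, length(t) - 1000)     # avoid edge transients
  amp <- function(v) sqrt(2 * mean(v^2))
  expect_equal(amp(y$Y[1, mid]), 1, tolerance = 0.1)
  expect_lt(amp(y$Y[2, mid]), 10^(-20 / 20))
  expect_error(bandpass(x, 13, 150), "fs/2")
  expect_error(bandpass(x, 0, 30), "fs/2")
})

test_that("band-passed white noise has its power inside the band", {
  fs <- 600
  set.seed(8)
  x <- sensor_data(matrix(rnorm(2 * 2^14), 2), fs)
  y <- bandpass(x, 13, 30)
  v <- y$Y[1, ]
  pw <- Mod(fft(v))^2
  freqs <- (seq_along(pw) - 1) * fs / length(pw)
  half <- freqs <= fs / 2
  inband <- half & freqs >= 10 & freqs <= 35
  expect_lt(sum(pw[half & !inband]) / sum(pw[half]), 0.05)
})

test_that("sensor data round-trips through the sidecar text format", {
  set.seed(6)
  x <- sensor_data(matrix(rnorm(12), 3), fs = 250,
                   channel_names = c("a", "b", "c"))
  f <- tempfile(fileext = ".tsv")
  write_sensor_data(x, f)
  y <- read_sensor_data(f)
  expect_equal(y$Y, x$Y, tolerance = 1e-9)
  expect_equal(y$fs, 250)
  expect_equal(y$channel_names, c("a", "b", "c"))
})
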