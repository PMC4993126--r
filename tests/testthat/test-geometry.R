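test_that("sensor helmet places the requested channels on the sphere", {
  sens <- make_sensor_helmet(274, 120, 0.6, seed = 1)
  expect_equal(nrow(sens$positions), 274)
  r <- sqrt(rowSums(sens$positions^2))
  expect_equal(r, rep(120, 274), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(sens$orientations^2)), rep(1, 274),
               tolerance = 1e-12)
  # radial orientations point along the position vectors
  expect_equal(sens$positions / 120, sens$orientations, tolerance = 1e-12)

  two <- make_sensor_helmet(2, 100, 1.0, seed = 3)
  expect_equal(nrow(two$positions), 2)

  expect_error(make_sensor_helmet(64, -5, 0.5), "radius")
  expect_error(make_sensor_helmet(64, 100, 1.5), "coverage")
  expect_error(make_sensor_helmet(1, 100, 0.5), "n_channels")
})

test_that("helmet spacing is within 30% of ideal uniform spacing", {
  sens <- make_sensor_helmet(64, 110, 0.5, seed = 7)
  u <- sens$orientations
  # brute-force pairwise angular distances
  cosang <- tcrossprod(u)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  ang <- acos(cosang)
  diag(ang) <- Inf
  min_spacing <- min(ang)
  # hexagonal-packing ideal: area per point = sqrt(3)/2 * d^2 on a cap of
  # solid angle 4*pi*coverage
  ideal <- sqrt(2 * (4 * pi * 0.5) / (sqrt(3) * 64))
  expect_gt(min_spacing, 0.7 * ideal)
})

test_that("cortical surrogate is a closed triangulated surface", {
  sp <- make_cortical_surrogate(162, radii = c(70, 70, 70))
  expect_equal(nrow(sp$vertices), 162)
  expect_equal(nrow(sp$faces), 320)
  # Euler characteristic of a closed surface: V - E + F = 2
  edges <- unique(t(apply(rbind(sp$faces[, 1:2], sp$faces[, 2:3],
                                sp$faces[, c(3, 1)]), 1, sort)))
  expect_equal(nrow(sp$vertices) - nrow(edges) + nrow(sp$faces), 2)
  expect_true(all(sp$faces <= nrow(sp$vertices)))
  expect_equal(sp$adjacency, t(sp$adjacency))
  expect_equal(sqrt(rowSums(sp$normals^2)), rep(1, 162), tolerance = 1e-12)

  ell <- make_cortical_surrogate(162)
  expect_true(all(sqrt(rowSums(ell$vertices^2)) <= max(c(70, 85, 65)) + 1e-9))
  expect_error(make_cortical_surrogate(4), "n_vertices")
})

test_that("nearest-vertex snapping matches exhaustive search", {
  sp <- make_cortical_surrogate(162)
  p <- c(41, -25, 49)
  idx <- snap_vertices(sp, p)
  d2 <- rowSums(sweep(sp$vertices, 2, p, "-")^2)
  expect_equal(idx, which.min(d2))
  expect_equal(d2[idx], min(d2))
  # several points at once, each verified exhaustively
  pts <- confound_coordinates()
  got <- snap_vertices(sp, pts)
  for (i in seq_len(nrow(pts))) {
    d2 <- rowSums(sweep(sp$vertices, 2, pts[i, ], "-")^2)
    expect_equal(got[i], which.min(d2))
  }
})

test_that("displace_head is a pure translation with an inverse", {
  sp <- tiny_space()
  expect_equal(displace_head(sp, c(0, 0, 0))$vertices, sp$vertices)
  back <- displace_head(displace_head(sp, c(5, 0, 0)), c(-5, 0, 0))
  expect_equal(back$vertices, sp$vertices, tolerance = 1e-12)
  up <- displace_head(sp, c(0, 0, 10))
  expect_equal(up$vertices[, 3], sp$vertices[, 3] + 10)
  expect_equal(up$vertices[, 1:2], sp$vertices[, 1:2])
  expect_equal(up$normals, sp$normals)
  expect_equal(up$faces, sp$faces)
  expect_error(displace_head(sp, c(1, NA, 0)), "finite")
})

test_that("radial dipoles are silent in the spherical conductor", {
  sphere <- make_cortical_surrogate(42, radii = c(70, 70, 70))
  sens <- tiny_sensors()
  lf <- leadfield_sphere(sphere, sens)
  scale <- max(abs(leadfield_sphere(tiny_space(), sens)$gain))
  expect_lt(max(abs(lf$gain)), 1e-12 * scale)
})

test_that("lead field is linear in the dipole moment", {
  sp <- tiny_space()
  sens <- tiny_sensors()
  lf1 <- leadfield_sphere(sp, sens)
  sp2 <- sp
  sp2$normals <- sp$normals * 2
  lf2 <- leadfield_sphere(sp2, sens)
  expect_equal(lf2$gain, 2 * lf1$gain, tolerance = 1e-12)
})

test_that("sphere solution matches the free-space radial-field oracle", {
  # For radially oriented sensors concentric with the conductor, the
  # conductor's volume currents contribute no radial field, so the gain
  # must equal the radial component of the free-space field of the
  # primary current dipole: (q x (r - r0)) . r / |r - r0|^3 / |r|.
  sp <- tiny_space()
  sens <- tiny_sensors()
  lf <- leadfield_sphere(sp, sens, centre = c(0, 0, 0))
  oracle <- matrix(0, nrow(sens$positions), nrow(sp$vertices))
  for (d in seq_len(nrow(sp$vertices))) {
    q <- sp$normals[d, ]; r0 <- sp$vertices[d, ]
    for (c in seq_len(nrow(sens$positions))) {
      r <- sens$positions[c, ]
      a <- r - r0
      qxa <- c(q[2] * a[3] - q[3] * a[2],
               q[3] * a[1] - q[1] * a[3],
               q[1] * a[2] - q[2] * a[1])
      oracle[c, d] <- sum(qxa * r) / (sqrt(sum(a^2))^3 * sqrt(sum(r^2)))
    }
  }
  expect_equal(lf$gain, oracle, tolerance = 1e-9)
})

test_that("gain decays as a tangential dipole moves toward the centre", {
  sens <- tiny_sensors()
  depths <- seq(60, 5, by = -5)
  norms <- vapply(depths, function(r) {
    sp <- structure(list(
      vertices = matrix(c(r, 0, 0), 1, 3),
      normals = matrix(c(0, 0, 1), 1, 3),
      faces = matrix(integer(0), 0, 3),
      adjacency = matrix(0, 1, 1)), class = "source_space")
    # fix the conductor to a common sphere so only source depth varies
    lf <- leadfield_sphere(sp, sens, centre = c(0, 0, 0), radius = 90)
    sqrt(sum(lf$gain^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("lead field changes under displacement and validates geometry", {
  sp <- tiny_space()
  sens <- tiny_sensors()
  lf0 <- leadfield_sphere(sp, sens)
  lf0b <- leadfield_sphere(displace_head(sp, c(0, 0, 0)), sens)
  expect_equal(lf0$gain, lf0b$gain)
  lf1 <- leadfield_sphere(displace_head(sp, c(5, 0, 0)), sens)
  expect_gt(max(abs(lf1$gain - lf0$gain)), 0)
  # sensors inside the conductor are rejected
  close_sens <- make_sensor_helmet(8, 50, 0.6, seed = 1)
  expect_error(leadfield_sphere(sp, close_sens), "outside")
})

test_that("sensor arrays and source spaces round-trip through text files", {
  sens <- tiny_sensors(8)
  f <- tempfile(fileext = ".tsv")
  write_sensor_array(sens, f)
  back <- read_sensor_array(f)
  expect_equal(back$positions, sens$positions, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$channel_names, sens$channel_names)

  sp <- tiny_space()
  stem <- tempfile()
  write_source_space(sp, stem)
  sp2 <- read_source_space(stem)
  expect_equal(sp2$vertices, sp$vertices, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sp2$faces, sp$faces, ignore_attr = TRUE)
  expect_equal(sp2$adjacency, sp$adjacency)
})
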