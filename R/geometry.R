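#' Sensor arrays, source spaces and the spherical MEG forward model
#'
#' The forward model ties dipolar current sources on a cortical surface to
#' the magnetic field measured by an array of sensors.  Head position enters
#' the model as a rigid translation of the source space relative to the
#' fixed sensor array; every candidate position therefore implies its own
#' lead-field matrix.
#'
#' @name megscan-geometry
NULL

golden_angle <- pi * (3 - sqrt(5))

#' Quasi-uniform sensor helmet on a spherical cap
#'
#' Places \code{n_channels} radially-oriented magnetometers on a spherical
#' cap using a Fibonacci lattice, emulating a whole-head MEG helmet.
#' \code{coverage} is the fraction of the full solid angle covered by the
#' cap (1 covers the whole sphere); the cap is centred on +z, where the top
#' of the head sits.
#'
#' @param n_channels number of sensors (>= 2).
#' @param radius helmet radius in mm; must exceed the conductor radius of
#'   any source space used with it.
#' @param coverage fraction of the sphere's solid angle in (0, 1].
#' @param seed integer seed; randomises the azimuthal phase of the lattice.
#' @return an object of class \code{sensor_array} with fields
#'   \code{positions} (C x 3, mm), \code{orientations} (C x 3 unit radial
#'   vectors) and \code{channel_names}.
#' @export
make_sensor_helmet <- function(n_channels, radius, coverage = 0.6, seed = 1L) {
  if (!is.numeric(n_channels) || n_channels < 2)
    stop("n_channels must be >= 2")
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be positive")
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]")
  n <- as.integer(n_channels)
  phase <- with_seed(as.integer(seed), stats::runif(1, 0, 2 * pi))
  i <- seq_len(n)
  # z descends from the pole over the cap; cap height = 2 * coverage
  z <- 1 - 2 * coverage * (i - 0.5) / n
  phi <- golden_angle * i + phase
  rho <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(rho * cos(phi), rho * sin(phi), z)
  structure(list(
    positions = u * radius,
    orientations = u,
    channel_names = sprintf("MEG%03d", i)
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  r <- sqrt(rowSums(x$positions^2))
  cat(sprintf("<sensor_array> %d channels, radius %.1f mm\n",
              nrow(x$positions), mean(r)))
  invisible(x)
}

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6),  c(1, 6, 2),   c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10),  c(6, 12, 5),  c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5),  c(4, 5, 3),   c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6),  c(3, 5, 12),  c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midpoint_cache <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j), sep = "_")
    idx <- midpoint_cache[[key]]
    if (!is.null(idx)) return(idx)
    m <- (verts[[i]] + verts[[j]]) / 2
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1]] <<- m
    idx <- length(verts)
    midpoint_cache[[key]] <- idx
    idx
  }
  new_faces <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    new_faces[4 * k - 3, ] <- c(a, ab, ca)
    new_faces[4 * k - 2, ] <- c(b, bc, ab)
    new_faces[4 * k - 1, ] <- c(c, ca, bc)
    new_faces[4 * k, ]     <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, verts), faces = new_faces)
}

adjacency_from_faces <- function(faces, n_vertices) {
  A <- matrix(0, n_vertices, n_vertices)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  A[e] <- 1
  A[e[, c(2, 1)]] <- 1
  A
}

#' Ellipsoidal surrogate cortical surface
#'
#' Builds a closed triangulated ellipsoid by icosahedral subdivision of the
#' unit sphere, scaled by the given semi-axes.  Dipole orientations are the
#' outward surface normals.  Achievable vertex counts are 12, 42, 162, 642,
#' 2562, ...; the level nearest to \code{n_vertices} is used.  An ellipsoid
#' (rather than a sphere) keeps the normal-oriented dipoles from being
#' purely radial, which would silence them in a spherical conductor.
#'
#' @param n_vertices requested number of vertices (>= 12).
#' @param radii semi-axes in mm along x, y, z.  Defaults approximate adult
#'   brain half-dimensions.
#' @param seed integer seed, reserved for randomised mesh variants; the
#'   icosphere itself is deterministic.
#' @return an object of class \code{source_space} with fields
#'   \code{vertices} (D x 3 mm), \code{normals} (D x 3 unit vectors),
#'   \code{faces} (triangle index matrix) and \code{adjacency}
#'   (D x D 0/1 matrix).
#' @export
make_cortical_surrogate <- function(n_vertices, radii = c(70, 85, 65), seed = 1L) {
  if (!is.numeric(n_vertices) || n_vertices < 12)
    stop("n_vertices must be >= 12")
  if (length(radii) == 1) radii <- rep(radii, 3)
  if (length(radii) != 3 || any(radii <= 0))
    stop("radii must be three positive semi-axes (mm)")
  mesh <- icosahedron()
  counts <- 12L
  meshes <- list(mesh)
  while (utils::tail(counts, 1) < n_vertices) {
    mesh <- subdivide_mesh(mesh)
    meshes[[length(meshes) + 1]] <- mesh
    counts <- c(counts, nrow(mesh$vertices))
  }
  pick <- which.min(abs(counts - n_vertices))
  mesh <- meshes[[pick]]
  v <- sweep(mesh$vertices, 2, radii, "*")
  # outward ellipsoid normal at (x,y,z): (x/a^2, y/b^2, z/c^2), normalized
  nrm <- sweep(mesh$vertices, 2, radii, "/")
  nrm <- nrm / sqrt(rowSums(nrm^2))
  structure(list(
    vertices = v,
    normals = nrm,
    faces = mesh$faces,
    adjacency = adjacency_from_faces(mesh$faces, nrow(v)),
    radii = radii
  ), class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Rigid head translation
#'
#' @param offset length-3 translation in mm of the head (source space)
#'   relative to the fixed sensors.
#' @param label optional identifier (e.g. "x+5").
#' @return an object of class \code{head_transform}.
#' @export
head_transform <- function(offset = c(0, 0, 0), label = NULL) {
  offset <- as.numeric(offset)
  if (length(offset) != 3 || any(!is.finite(offset)))
    stop("offset must be a finite 3-vector")
  structure(list(offset = offset, label = label), class = "head_transform")
}

#' Apply a head translation to a source space
#'
#' Translates every vertex by the transform's offset; normals, faces and
#' adjacency are unchanged (rigid translation).
#'
#' @param space a \code{source_space}.
#' @param transform a \code{head_transform} or a length-3 offset in mm.
#' @return the displaced \code{source_space}.
#' @export
displace_head <- function(space, transform) {
  stopifnot(inherits(space, "source_space"))
  if (!inherits(transform, "head_transform")) transform <- head_transform(transform)
  space$vertices <- sweep(space$vertices, 2, transform$offset, "+")
  space$transform <- transform
  space
}

#' Conductor sphere for a source space
#'
#' Default conductor model parameters: centre at the source-space centroid,
#' radius 1.1 times the maximal centre-to-vertex distance.
#'
#' @param space a \code{source_space}.
#' @return list with \code{centre} (3-vector, mm) and \code{radius} (mm).
#' @export
conductor_sphere <- function(space) {
  centre <- colMeans(space$vertices)
  d <- sqrt(rowSums(sweep(space$vertices, 2, centre, "-")^2))
  list(centre = centre, radius = 1.1 * max(d))
}

#' Snap points to their nearest mesh vertices
#'
#' Euclidean nearest-vertex lookup; ties are broken by the lowest vertex
#' index.  Used to place named source coordinates on the mesh.
#'
#' @param space a \code{source_space}.
#' @param points n x 3 matrix (or length-3 vector) of coordinates in mm.
#' @return integer vector of vertex indices.
#' @export
snap_vertices <- function(space, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  apply(points, 1, function(p) {
    d2 <- rowSums(sweep(space$vertices, 2, p, "-")^2)
    which.min(d2)  # which.min takes the first (lowest-index) minimiser
  })
}

#' Lead field of the homogeneous conducting sphere
#'
#' Computes the magnetic field at each sensor, along its orientation, for a
#' unit dipole at each source vertex oriented along its surface normal,
#' using the closed-form solution for a current dipole inside a homogeneous
#' conducting sphere (primary plus volume currents).  Radially oriented
#' dipoles produce no external field in this model.  Field units are
#' arbitrary (the constant mu0/4pi is dropped); all downstream inference is
#' invariant to this global scale.
#'
#' @param space a \code{source_space} (all vertices strictly inside the
#'   conductor).
#' @param sensors a \code{sensor_array} (all positions strictly outside).
#' @param centre optional conductor centre; defaults to
#'   \code{conductor_sphere(space)$centre}.
#' @param radius optional conductor radius override (mm).
#' @return an object of class \code{lead_field} with fields \code{gain}
#'   (C x D), \code{transform} and \code{conductor}.
#' @export
leadfield_sphere <- function(space, sensors, centre = NULL, radius = NULL) {
  stopifnot(inherits(space, "source_space"), inherits(sensors, "sensor_array"))
  cond <- conductor_sphere(space)
  if (!is.null(centre)) cond$centre <- as.numeric(centre)
  if (!is.null(radius)) cond$radius <- as.numeric(radius)
  rs <- sweep(sensors$positions, 2, cond$centre, "-")       # sensors rel. centre
  sensor_norm <- sqrt(rowSums(rs^2))
  if (any(sensor_norm <= cond$radius))
    stop("all sensors must lie strictly outside the conductor sphere")
  r0 <- sweep(space$vertices, 2, cond$centre, "-")          # sources rel. centre
  src_norm <- sqrt(rowSums(r0^2))
  if (any(src_norm >= cond$radius))
    stop("all sources must lie strictly inside the conductor sphere")
  if (any(src_norm < 1e-9))
    stop("source at the conductor centre has no defined tangential field")
  C <- nrow(rs); D <- nrow(r0)
  gain <- matrix(0, C, D)
  orient <- sensors$orientations
  rn <- sensor_norm
  for (d in seq_len(D)) {
    q <- space$normals[d, ]
    p <- r0[d, ]
    a <- sweep(rs, 2, p, "-")                               # C x 3
    an <- sqrt(rowSums(a^2))
    ar <- rowSums(a * rs)
    r0r <- as.numeric(rs %*% p)
    FF <- an * (rn * an + rn^2 - r0r)
    coef_r <- an^2 / rn + ar / an + 2 * an + 2 * rn
    coef_p <- an + 2 * rn + ar / an
    gradF <- rs * coef_r - matrix(p, C, 3, byrow = TRUE) * coef_p
    qxp <- c(q[2] * p[3] - q[3] * p[2],
             q[3] * p[1] - q[1] * p[3],
             q[1] * p[2] - q[2] * p[1])                     # q x r0
    qxp_r <- as.numeric(rs %*% qxp)
    B <- (matrix(qxp, C, 3, byrow = TRUE) * FF - gradF * qxp_r) / FF^2
    gain[, d] <- rowSums(B * orient)
  }
  if (any(!is.finite(gain))) stop("non-finite lead field entries")
  structure(list(
    gain = gain,
    transform = space$transform %||% head_transform(),
    conductor = cond,
    channel_names = sensors$channel_names
  ), class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d sources (sphere r = %.1f mm)\n",
              nrow(x$gain), ncol(x$gain), x$conductor$radius))
  invisible(x)
}

#' Write / read a sensor array as a plain-text table
#'
#' One row per sensor: name, x, y, z, nx, ny, nz (tab-separated).
#' @param x a \code{sensor_array}.
#' @param path file path.
#' @export
write_sensor_array <- function(x, path) {
  df <- data.frame(name = x$channel_names,
                   x$positions, x$orientations)
  names(df) <- c("name", "x", "y", "z", "nx", "ny", "nz")
  utils::write.table(format_numeric_df(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(list(
    positions = as.matrix(df[, c("x", "y", "z")]),
    orientations = as.matrix(df[, c("nx", "ny", "nz")]),
    channel_names = df$name
  ), class = "sensor_array")
}

#' Write / read a source space as plain-text tables
#'
#' Writes vertices+normals to \code{<stem>_vertices.tsv} and faces to
#' \code{<stem>_faces.tsv}.
#' @param x a \code{source_space}.
#' @param stem path stem (without suffix).
#' @export
write_source_space <- function(x, stem) {
  dfv <- data.frame(x$vertices, x$normals)
  names(dfv) <- c("x", "y", "z", "nx", "ny", "nz")
  utils::write.table(format_numeric_df(dfv), paste0(stem, "_vertices.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dff <- data.frame(x$faces)
  names(dff) <- c("v1", "v2", "v3")
  utils::write.table(dff, paste0(stem, "_faces.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_source_space
#' @export
read_source_space <- function(stem) {
  dfv <- utils::read.table(paste0(stem, "_vertices.tsv"), header = TRUE, sep = "\t")
  dff <- utils::read.table(paste0(stem, "_faces.tsv"), header = TRUE, sep = "\t")
  faces <- as.matrix(dff)
  storage.mode(faces) <- "integer"
  structure(list(
    vertices = as.matrix(dfv[, c("x", "y", "z")]),
    normals = as.matrix(dfv[, c("nx", "ny", "nz")]),
    faces = faces,
    adjacency = adjacency_from_faces(faces, nrow(dfv))
  ), class = "source_space")
}
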