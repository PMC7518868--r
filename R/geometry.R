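#' Subdivided icosahedral sphere mesh
#'
#' Builds a triangulated unit sphere by repeated 4-to-1 subdivision of an
#' icosahedron, projecting new vertices back to the sphere. A mesh at
#' subdivision level `s` has `10 * 4^s + 2` vertices.
#'
#' @param subdivisions Non-negative integer subdivision level.
#' @param radius Sphere radius (mm). Vertex coordinates are scaled by this.
#' @return A list of class `cortex_mesh` with `vertices` (n x 3 matrix, mm)
#'   and `faces` (m x 3 integer matrix of vertex indices).
#' @export
icosphere <- function(subdivisions = 4, radius = 1) {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(subdivisions)) {
    n_v <- nrow(v)
    edge_key <- function(i, j) ifelse(i < j, i * (n_v + 1) + j, j * (n_v + 1) + i)
    # all edges of all faces; midpoint index assigned once per undirected edge
    e1 <- c(f[, 1], f[, 2], f[, 3])
    e2 <- c(f[, 2], f[, 3], f[, 1])
    keys <- edge_key(e1, e2)
    uk <- unique(keys)
    mid_of <- match(keys, uk) + n_v
    ui <- match(uk, keys)
    mids <- (v[e1[ui], , drop = FALSE] + v[e2[ui], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m <- nrow(f)
    a <- mid_of[seq_len(m)]
    b <- mid_of[m + seq_len(m)]
    c_ <- mid_of[2 * m + seq_len(m)]
    f <- rbind(
      cbind(f[, 1], a, c_),
      cbind(f[, 2], b, a),
      cbind(f[, 3], c_, b),
      cbind(a, b, c_)
    )
  }
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  structure(list(vertices = v * radius, faces = f), class = "cortex_mesh")
}

#' Fibonacci lattice on a band of the sphere
#'
#' Quasi-uniform points whose coordinate along `axis` is an even grid on
#' `[-(1 - cap), (1 - cap)]`, rotated by the golden angle. With `cap = 0`
#' this is the classic whole-sphere Fibonacci lattice.
#'
#' @param n Number of points.
#' @param cap Height of the excluded polar caps along `axis` (0 to < 1).
#' @param axis Which coordinate (1, 2, 3) carries the lattice axis.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_lattice <- function(n, cap = 0, axis = 1) {
  stopifnot(n >= 1, cap >= 0, cap < 1)
  i <- seq_len(n) - 0.5
  x <- (1 - cap) * (1 - 2 * i / n)
  r <- sqrt(pmax(0, 1 - x^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  pts <- matrix(0, n, 3)
  others <- setdiff(1:3, axis)
  pts[, axis] <- x
  pts[, others[1]] <- r * cos(theta)
  pts[, others[2]] <- r * sin(theta)
  pts
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex one-ring (barycentric) areas
#'
#' Each face contributes one third of its area to each of its vertices.
#'
#' @param mesh A `cortex_mesh`.
#' @return Numeric vector of vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh) / 3
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  agg <- rowsum(rep(fa, 3), c(mesh$faces))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
    mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

#' Synthetic spherical parcellation with twin-study geometry
#'
#' Builds an icosphere, carves out a medial-wall polar cap at each pole of the
#' left/right split axis (x), places `n_parcels` quasi-uniform parcel seeds on
#' the remaining band by a Fibonacci lattice, and assigns every non-wall
#' vertex to the nearest same-hemisphere seed (spherical Voronoi cells).
#' Community labels partition parcels into `n_communities` contiguous groups,
#' and two near-antipodal vertex sets per hemisphere mark the archicortical
#' (superior/posterior-medial) and paleocortical (inferior/anterior-medial)
#' origins used by dual-origin distance analyses.
#'
#' @param n_parcels Total number of parcels (>= 4; split across hemispheres).
#' @param mesh_resolution Icosphere subdivision level; must give at least
#'   `10 * n_parcels` vertices.
#' @param seed Integer seed (kept for interface stability; construction is
#'   deterministic).
#' @param radius Sphere radius in mm.
#' @param medial_wall Height of each excluded polar cap (fraction of unit
#'   coordinate; default 0.06).
#' @param n_communities Number of community labels (default 7).
#' @param n_seed_vertices Vertices per origin seed set (default 6).
#' @return A `parcel_geometry` list: `parcel_id`, `hemisphere` ("L"/"R"),
#'   `centroid` (p x 3 unit vectors), `community`, `mesh`, `vertex_to_parcel`
#'   (NA for medial wall), `seed_points` (named vertex-index sets), `radius`.
#' @export
make_sphere_parcellation <- function(n_parcels, mesh_resolution = 4, seed = 1L,
                                     radius = 70, medial_wall = 0.06,
                                     n_communities = 7, n_seed_vertices = 6) {
  stopifnot(n_parcels >= 4)
  mesh <- icosphere(mesh_resolution, radius = radius)
  n_v <- nrow(mesh$vertices)
  if (n_v < 10 * n_parcels) {
    stop("mesh_resolution ", mesh_resolution, " gives ", n_v,
      " vertices; need at least 10 * n_parcels = ", 10 * n_parcels,
      call. = FALSE
    )
  }
  unit_v <- mesh$vertices / radius
  wall <- abs(unit_v[, 1]) > (1 - medial_wall)
  seeds <- fibonacci_lattice(n_parcels, cap = medial_wall, axis = 1)
  seed_hemi <- ifelse(seeds[, 1] >= 0, "L", "R")
  vert_hemi <- ifelse(unit_v[, 1] >= 0, "L", "R")

  v2p <- rep(NA_integer_, n_v)
  for (h in c("L", "R")) {
    sv <- which(vert_hemi == h & !wall)
    sp <- which(seed_hemi == h)
    sim <- unit_v[sv, , drop = FALSE] %*% t(seeds[sp, , drop = FALSE])
    v2p[sv] <- sp[max.col(sim, ties.method = "first")]
  }
  counts <- tabulate(v2p, nbins = n_parcels)
  if (any(counts == 0)) {
    stop("parcel(s) with zero vertices: ", paste(which(counts == 0), collapse = ", "),
      call. = FALSE
    )
  }
  cent <- rowsum(unit_v[!is.na(v2p), , drop = FALSE], v2p[!is.na(v2p)])
  cent <- cent / sqrt(rowSums(cent^2))
  hemi <- ifelse(cent[, 1] >= 0, "L", "R")

  comm_dirs <- fibonacci_lattice(n_communities, axis = 3)
  community <- max.col(cent %*% t(comm_dirs), ties.method = "first")

  seed_points <- list()
  for (h in c("L", "R")) {
    s <- if (h == "L") 1 else -1
    archi_dir <- c(0.35 * s, -0.25, 0.9)
    paleo_dir <- c(0.35 * s, 0.25, -0.9)
    for (nm in c("archicortex", "paleocortex")) {
      d <- if (nm == "archicortex") archi_dir else paleo_dir
      d <- d / sqrt(sum(d^2))
      ok <- which(!wall & vert_hemi == h)
      sim <- unit_v[ok, , drop = FALSE] %*% d
      seed_points[[paste0(nm, "_", h)]] <-
        ok[order(sim, decreasing = TRUE)[seq_len(n_seed_vertices)]]
    }
  }
  seed_points$archicortex <- c(seed_points$archicortex_L, seed_points$archicortex_R)
  seed_points$paleocortex <- c(seed_points$paleocortex_L, seed_points$paleocortex_R)

  structure(
    list(
      parcel_id = seq_len(n_parcels),
      hemisphere = hemi,
      centroid = cent,
      community = community,
      mesh = mesh,
      vertex_to_parcel = v2p,
      seed_points = seed_points,
      radius = radius
    ),
    class = "parcel_geometry"
  )
}

#' @export
print.parcel_geometry <- function(x, ...) {
  cat(
    "<parcel_geometry> ", length(x$parcel_id), " parcels (",
    sum(x$hemisphere == "L"), " L / ", sum(x$hemisphere == "R"), " R), ",
    nrow(x$mesh$vertices), " vertices, ",
    sum(is.na(x$vertex_to_parcel)), " medial-wall vertices\n",
    sep = ""
  )
  invisible(x)
}

#' Parcel metadata as a tibble
#'
#' @param x A `parcel_geometry`.
#' @param ... Unused.
#' @return Tibble with one row per parcel: id, hemisphere, community,
#'   centroid coordinates, and vertex count.
#' @export
tidy.parcel_geometry <- function(x, ...) {
  tibble::tibble(
    parcel_id = x$parcel_id,
    hemisphere = x$hemisphere,
    community = x$community,
    cx = x$centroid[, 1],
    cy = x$centroid[, 2],
    cz = x$centroid[, 3],
    n_vertices = tabulate(x$vertex_to_parcel, nbins = length(x$parcel_id))
  )
}
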