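mesh_graph <- function(mesh, vertices = NULL) {
  ed <- if (!is.null(mesh$edges)) {
    list(
      edges = mesh$edges,
      lengths = sqrt(rowSums((mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
        mesh$vertices[mesh$edges[, 2], , drop = FALSE])^2))
    )
  } else {
    mesh_edges(mesh)
  }
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  igraph::E(g)$weight <- ed$lengths
  n <- nrow(mesh$vertices)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (!is.null(vertices)) g <- igraph::induced_subgraph(g, vertices)
  g
}

#' Geodesic distance over a triangle mesh
#'
#' Shortest-path distance along mesh edges (Dijkstra with edge lengths) from
#' a source vertex set; the distance at each vertex is to its nearest source.
#'
#' @param mesh A `cortex_mesh` (or list with `vertices` and `faces`/`edges`).
#' @param sources Integer vertex indices.
#' @param vertices Optional vertex subset to restrict the graph to (e.g. one
#'   hemisphere); distances are computed within the subset and returned on
#'   the full vertex indexing (NA outside).
#' @return Numeric vector of distances (mm), NA for unreachable vertices
#'   outside `vertices`; errors if vertices inside the subset are
#'   unreachable.
#' @export
geodesic_distance <- function(mesh, sources, vertices = NULL) {
  n <- nrow(mesh$vertices)
  out <- rep(NA_real_, n)
  if (is.null(vertices)) vertices <- seq_len(n)
  sources_in <- intersect(sources, vertices)
  if (length(sources_in) == 0) stop("no sources inside the vertex subset", call. = FALSE)
  g <- mesh_graph(mesh, vertices)
  d <- igraph::distances(g, v = match(sources_in, vertices), mode = "all")
  dmin <- apply(d, 2, min)
  if (any(!is.finite(dmin))) {
    comp <- igraph::components(g)
    stop(
      "unreachable vertices; graph has ", comp$no, " components of sizes ",
      paste(comp$csize, collapse = ", "),
      call. = FALSE
    )
  }
  out[vertices] <- dmin
  out
}

#' Per-parcel geodesic distances from the archi- and paleocortex origins
#'
#' Distances are computed per hemisphere (ipsilateral paths only, using each
#' hemisphere's origin seed vertices) and averaged over each parcel's
#' vertices.
#'
#' @param geom A `parcel_geometry`.
#' @return A `distance_fields` list: `archicortex_distance`,
#'   `paleocortex_distance` (per-parcel, mm), and `vertex` versions.
#' @export
origin_distance_fields <- function(geom) {
  v2p <- geom$vertex_to_parcel
  unit_x <- geom$mesh$vertices[, 1]
  vert_hemi <- ifelse(unit_x >= 0, "L", "R")
  p <- length(geom$parcel_id)
  out <- list()
  for (nm in c("archicortex", "paleocortex")) {
    dv <- rep(NA_real_, length(v2p))
    for (h in c("L", "R")) {
      vs <- which(vert_hemi == h)
      src <- geom$seed_points[[paste0(nm, "_", h)]]
      dv[vs] <- geodesic_distance(geom$mesh, src, vertices = vs)[vs]
    }
    dp <- vapply(seq_len(p), function(k) mean(dv[which(v2p == k)]), numeric(1))
    out[[paste0(nm, "_distance")]] <- dp
    out[[paste0(nm, "_vertex")]] <- dv
  }
  structure(out, class = "distance_fields")
}

#' Ipsilateral parcel-to-parcel geodesic distance matrix
#'
#' Distances between parcel representative vertices (nearest mesh vertex to
#' each centroid), computed within each hemisphere's subgraph;
#' cross-hemisphere entries are NA.
#'
#' @param geom A `parcel_geometry`.
#' @return A `parcel_matrix` of kind `"distance"` with NA across hemispheres.
#' @export
geodesic_parcel_matrix <- function(geom) {
  p <- length(geom$parcel_id)
  unit_v <- geom$mesh$vertices / geom$radius
  rep_vertex <- vapply(seq_len(p), function(k) {
    vs <- which(geom$vertex_to_parcel == k)
    vs[which.max(unit_v[vs, , drop = FALSE] %*% geom$centroid[k, ])]
  }, integer(1))
  dmat <- matrix(NA_real_, p, p)
  vert_hemi <- ifelse(geom$mesh$vertices[, 1] >= 0, "L", "R")
  for (h in c("L", "R")) {
    pk <- which(geom$hemisphere == h)
    vs <- which(vert_hemi == h)
    g <- mesh_graph(geom$mesh, vs)
    reps <- match(rep_vertex[pk], vs)
    dmat[pk, pk] <- igraph::distances(g, v = reps, to = reps, mode = "all")
  }
  diag(dmat) <- 0
  parcel_matrix(dmat, kind = "distance", parcel_ids = paste0("p", geom$parcel_id))
}

random_rotation <- function() {
  a <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(a)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Precompute spin-test rotations and parcel reassignments
#'
#' Draws uniform random rotations of the sphere; the right hemisphere uses
#' the left rotation mirrored across the x = 0 plane. Under each rotation
#' every original parcel is matched to a rotated same-hemisphere centroid.
#' The default (`"nearest"`, the map-resampling variant) lets several
#' parcels borrow the same source parcel; `"bijective"` instead builds a
#' greedy one-to-one matching so each null map is an exact permutation of
#' the original values, at the cost of scrambling parcels displaced into
#' the medial wall, which makes the test markedly anticonservative on
#' smooth maps — it is provided for permutation-property use, not as the
#' better-calibrated default. The result depends only on the geometry, so
#' it can be reused across many tests of different map pairs.
#'
#' @param geom A `parcel_geometry`.
#' @param n_rotations Number of rotations (default 1000).
#' @param seed Integer seed.
#' @param assignment `"nearest"` (default) or `"bijective"`.
#' @return A `spin_null`: `assignments` (n_rotations x p index matrix),
#'   `rotations` (list of 3x3 matrices), `seed`, `assignment`.
#' @export
spin_permutations <- function(geom, n_rotations = 1000, seed = 1L,
                              assignment = c("nearest", "bijective")) {
  assignment <- match.arg(assignment)
  set.seed(seed)
  cent <- geom$centroid
  p <- nrow(cent)
  hemi <- geom$hemisphere
  left <- which(hemi == "L")
  right <- which(hemi == "R")
  rotations <- lapply(seq_len(n_rotations), function(b) random_rotation())
  assignments <- .spin_assign_batch(
    cent, left, right, rotations,
    assignment == "bijective"
  )
  structure(
    list(
      assignments = assignments, rotations = rotations, seed = seed,
      assignment = assignment
    ),
    class = "spin_null"
  )
}

#' @export
print.spin_null <- function(x, ...) {
  cat(
    "<spin_null> ", nrow(x$assignments), " rotations x ",
    ncol(x$assignments), " parcels (seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Spin permutation test for correlated spatial maps
#'
#' Correlates two parcel maps and assesses significance against a null in
#' which one map is resampled under random rotations of the spherical parcel
#' centroids (preserving spatial autocorrelation). Two-tailed
#' `p = (1 + #{|r_null| >= |r_obs|}) / (n_rotations + 1)`.
#'
#' @param map_a,map_b Numeric parcel vectors.
#' @param geom A `parcel_geometry` (ignored when `spins` is given).
#' @param n_rotations Number of rotations.
#' @param seed Integer seed.
#' @param spins Optional precomputed [spin_permutations()] result.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `r_observed`, `p_spin`, `null_r`, `n_rotations`, `method`.
#' @export
spin_test <- function(map_a, map_b, geom = NULL, n_rotations = 1000, seed = 1L,
                      spins = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("degenerate map: zero variance", call. = FALSE)
  }
  if (is.null(spins)) {
    if (is.null(geom)) stop("supply geom or precomputed spins", call. = FALSE)
    spins <- spin_permutations(geom, n_rotations, seed)
  }
  stopifnot(length(map_a) == ncol(spins$assignments), length(map_a) == length(map_b))
  r_obs <- stats::cor(map_a, map_b, method = method)
  null_maps <- matrix(map_a[t(spins$assignments)], nrow = length(map_a))
  null_r <- as.numeric(stats::cor(null_maps, map_b, method = method))
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (length(null_r) + 1)
  list(
    r_observed = r_obs, p_spin = p, null_r = null_r,
    n_rotations = nrow(spins$assignments), method = method
  )
}

energy_stat_from_parts <- function(s_aa, s_bb, s_ab, n, m, sign = 1) {
  # sign = 1: energy distance (cross minus within); sign = -1: the
  # minimum-energy (log-potential) statistic, where within-sample terms repel
  e <- sign * (2 * s_ab / (n * m) - s_aa / (n * n) - s_bb / (m * m))
  (n * m / (n + m)) * e
}

#' Energy two-sample test with a permutation null
#'
#' Energy distance between two samples of scalar values,
#' `E = 2 mean|a - b| - mean|a - a'| - mean|b - b'|` (means over all ordered
#' pairs), scaled by `n m / (n + m)`; significance by pooled relabelling.
#' `E >= 0`, with 0 iff the samples coincide. The `"log"` potential
#' (`-log d`) of the cited minimum-energy literature is available as an
#' option.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param potential `"euclidean"` (energy distance, default) or `"log"`.
#' @return List: `statistic`, `p_value`, `n_perm`, `potential`.
#' @export
energy_test <- function(sample_a, sample_b, n_perm = 1000, seed = 1L,
                        potential = c("euclidean", "log")) {
  potential <- match.arg(potential)
  n <- length(sample_a)
  m <- length(sample_b)
  if (n == 0 || m == 0) stop("both samples must be nonempty", call. = FALSE)
  if (n == 1 || m == 1) {
    warning("sample of size 1: its within-sample term is 0 by convention")
  }
  z <- c(sample_a, sample_b)
  d <- abs(outer(z, z, "-"))
  if (potential == "log") {
    eps <- 1e-12
    d <- -log(d + eps)
    diag(d) <- 0
  }
  stat_sign <- if (potential == "log") -1 else 1
  tot <- n + m
  ia <- seq_len(n)
  stat_for <- function(idx_a) {
    za <- logical(tot)
    za[idx_a] <- TRUE
    s_aa <- sum(d[za, za])
    s_bb <- sum(d[!za, !za])
    s_ab <- (sum(d) - s_aa - s_bb) / 2
    energy_stat_from_parts(s_aa, s_bb, s_ab, n, m, stat_sign)
  }
  obs <- stat_for(ia)
  set.seed(seed)
  # all permutations at once via indicator quadratic forms
  z_ind <- matrix(0, tot, n_perm)
  for (b in seq_len(n_perm)) z_ind[sample.int(tot, n), b] <- 1
  q_aa <- colSums(z_ind * (d %*% z_ind))
  q_bb <- colSums((1 - z_ind) * (d %*% (1 - z_ind)))
  s_ab <- (sum(d) - q_aa - q_bb) / 2
  null_stats <- energy_stat_from_parts(q_aa, q_bb, s_ab, n, m, stat_sign)
  p <- (1 + sum(null_stats >= obs)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = n_perm, potential = potential)
}

#' Correlation with a confidence interval
#'
#' Pearson correlations get a Fisher z-transform interval; Spearman
#' correlations a bootstrap percentile interval.
#'
#' @param map_a,map_b Numeric vectors of equal length >= 4.
#' @param method `"pearson"` or `"spearman"`.
#' @param ci_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates for Spearman.
#' @param seed Seed for the bootstrap.
#' @return Tibble: `r`, `ci_low`, `ci_high`, `method`, `degenerate`.
#' @export
correlate_with_ci <- function(map_a, map_b, method = c("pearson", "spearman"),
                              ci_level = 0.95, n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  n <- length(map_a)
  stopifnot(n == length(map_b), n >= 4)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  r <- stats::cor(map_a, map_b, method = method)
  degenerate <- abs(r) >= 1 - 1e-12
  if (method == "pearson") {
    if (degenerate) {
      lo <- hi <- r
    } else {
      zq <- stats::qnorm(1 - (1 - ci_level) / 2)
      z <- atanh(r)
      se <- 1 / sqrt(n - 3)
      lo <- tanh(z - zq * se)
      hi <- tanh(z + zq * se)
    }
  } else {
    set.seed(seed)
    boots <- replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      suppressWarnings(stats::cor(map_a[idx], map_b[idx], method = "spearman"))
    })
    qs <- stats::quantile(boots, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
      na.rm = TRUE, names = FALSE
    )
    lo <- qs[1]
    hi <- qs[2]
  }
  tibble::tibble(
    r = r, ci_low = lo, ci_high = hi,
    method = method, degenerate = degenerate
  )
}

#' Dual-origin association of a gradient with origin distance maps
#'
#' Two complementary views of whether a gradient follows the archicortical /
#' paleocortical differentiation waves: (i) the gradient is split at its
#' median and each origin-distance field is compared between the two halves
#' with an energy test; (ii) the gradient is correlated with each distance
#' field and assessed with a spin test.
#'
#' @param grad Numeric gradient scores (or a `gradient_set`, first column).
#' @param fields A `distance_fields` from [origin_distance_fields()].
#' @param geom A `parcel_geometry`.
#' @param n_rotations Spin rotations (also used as energy permutations).
#' @param seed Integer seed.
#' @param spins Optional precomputed spin permutations.
#' @param method Correlation method for the spin test.
#' @return Tibble: origin, energy_stat, p_energy, r, p_spin.
#' @export
dual_origin_association <- function(grad, fields, geom, n_rotations = 1000,
                                    seed = 1L, spins = NULL,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(grad, "gradient_set")) grad <- grad$coords[, 1]
  upper <- grad > stats::median(grad)
  if (is.null(spins)) spins <- spin_permutations(geom, n_rotations, seed)
  rows <- lapply(c("archicortex", "paleocortex"), function(nm) {
    f <- fields[[paste0(nm, "_distance")]]
    et <- energy_test(f[upper], f[!upper], n_perm = n_rotations, seed = seed)
    st <- spin_test(grad, f, spins = spins, method = method)
    tibble::tibble(
      origin = nm,
      energy_stat = et$statistic, p_energy = et$p_value,
      r = st$r_observed, p_spin = st$p_spin
    )
  })
  dplyr::bind_rows(rows)
}

#' Regress geodesic distance out of a covariance matrix
#'
#' For the within-hemisphere pairs, fits covariance values on
#' `[1, d, d^2]` by OLS and returns the residual matrix; cross-hemisphere
#' entries (no ipsilateral distance) pass through unchanged.
#'
#' @param mat A `parcel_matrix` (covariance-like).
#' @param distances A `parcel_matrix` of kind `"distance"` (NA across
#'   hemispheres).
#' @return A `parcel_matrix` of kind `"covariance"` of residuals.
#' @export
regress_distance <- function(mat, distances) {
  v <- pm_values(mat)
  d <- pm_values(distances)
  stopifnot(all(dim(v) == dim(d)))
  ut <- upper.tri(v)
  ok <- ut & !is.na(d)
  dd <- d[ok]
  if (stats::sd(dd) == 0) stop("constant distances: design rank deficient", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, dd, dd^2), v[ok])
  out <- v
  out[ok] <- fit$residuals
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 0
  parcel_matrix(out,
    kind = "covariance",
    parcel_ids = if (inherits(mat, "parcel_matrix")) mat$parcel_ids else NULL,
    meta = list(distance_regressed = TRUE)
  )
}
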