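#' Equivolumetric depth fraction
#'
#' Euclidean distance fraction `rho` between an outer and inner surface at
#' which an intracortical surface must sit so that the volume fraction
#' `alpha` between it and the outer surface is preserved under the local
#' surface-area change:
#' `rho = (-A_in + sqrt(alpha * A_out^2 + (1 - alpha) * A_in^2)) / (A_out - A_in)`,
#' with the continuous limit `rho = alpha` as `A_out -> A_in`.
#'
#' Vectorized over all three arguments.
#'
#' @param alpha Volume fraction(s) in [0, 1].
#' @param A_out,A_in Outer and inner surface areas (mm^2), positive.
#' @return Distance fraction(s) in [0, 1].
#' @export
equivolumetric_rho <- function(alpha, A_out, A_in) {
  if (any(A_out <= 0) || any(A_in <= 0)) stop("areas must be positive", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]", call. = FALSE)
  n <- max(length(alpha), length(A_out), length(A_in))
  alpha <- rep_len(alpha, n)
  A_out <- rep_len(A_out, n)
  A_in <- rep_len(A_in, n)
  rho <- numeric(n)
  eq <- abs(A_out - A_in) < 1e-12 * pmax(A_out, A_in)
  rho[eq] <- alpha[eq]
  ne <- !eq
  rho[ne] <- (-A_in[ne] + sqrt(alpha[ne] * A_out[ne]^2 + (1 - alpha[ne]) * A_in[ne]^2)) /
    (A_out[ne] - A_in[ne])
  rho
}

interp_rows <- function(values, depths, rho) {
  # per-row linear interpolation of `values` (rows x grid) at `rho` (per row)
  k <- findInterval(rho, depths, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1), length(depths) - 1)
  frac <- (rho - depths[k]) / (depths[k + 1] - depths[k])
  i <- seq_len(nrow(values))
  values[cbind(i, k)] * (1 - frac) + values[cbind(i, k + 1)] * frac
}

#' Synthetic intracortical intensity field
#'
#' Per-vertex depth profiles built from per-community polynomial templates
#' (base + slope * depth + curvature * depth^2) plus vertex-level Gaussian
#' noise, mimicking a myelin-sensitive contrast that varies smoothly with
#' depth and differs between cortical classes.
#'
#' @param geom A `parcel_geometry`.
#' @param n_depths Depth-grid resolution.
#' @param noise_sd Vertex-level noise SD (intensity units).
#' @param seed Integer seed.
#' @param templates Optional data frame with columns `base`, `slope`,
#'   `curvature`, one row per community; defaults drawn deterministically.
#' @return An `intensity_field`: `depths` grid, `values`
#'   (vertices x depths), `class` (per-vertex template id), `templates`.
#' @export
make_intensity_field <- function(geom, n_depths = 21, noise_sd = 0.1, seed = 1L,
                                 templates = NULL) {
  set.seed(seed)
  n_comm <- max(geom$community)
  if (is.null(templates)) {
    templates <- data.frame(
      base = 1 + 0.15 * seq_len(n_comm),
      slope = seq(-0.8, 0.8, length.out = n_comm),
      curvature = seq(0.5, -0.5, length.out = n_comm)
    )
  }
  depths <- seq(0, 1, length.out = n_depths)
  v2p <- geom$vertex_to_parcel
  cls <- rep(NA_integer_, length(v2p))
  cls[!is.na(v2p)] <- geom$community[v2p[!is.na(v2p)]]
  vals <- matrix(NA_real_, length(v2p), n_depths)
  ok <- which(!is.na(cls))
  tpl <- templates[cls[ok], , drop = FALSE]
  prof <- outer(tpl$base, rep(1, n_depths)) +
    outer(tpl$slope, depths) +
    outer(tpl$curvature, depths^2)
  vals[ok, ] <- prof + stats::rnorm(length(prof), 0, noise_sd)
  structure(
    list(depths = depths, values = vals, class = cls, templates = templates),
    class = "intensity_field"
  )
}

#' Sample equivolumetric depth profiles and average per parcel
#'
#' Places `n_surfaces` intracortical surfaces at equally spaced volume
#' fractions `alpha` between the bounding surfaces (`alpha = 0` and `rho = 0`
#' at one surface, `alpha = 1` and `rho = 1` at the other),
#' converts each to a per-vertex Euclidean depth with
#' [equivolumetric_rho()] using per-vertex one-ring areas of the outer and
#' inner surfaces, samples the intensity field at those depths (linear
#' interpolation over the field's depth grid), and averages per parcel.
#'
#' For the synthetic spherical cortex the inner surface is the mesh and the
#' outer surface is the mesh inflated by `thickness_mm`.
#'
#' @param intensity_field An `intensity_field` (or list with `depths` and
#'   `values`).
#' @param geom A `parcel_geometry`.
#' @param n_surfaces Number of surfaces (default 12).
#' @param thickness_mm Cortical thickness used to inflate the outer surface.
#' @param area_out,area_in Optional explicit per-vertex areas (mm^2).
#' @return A `profile_matrix`: `intensities` (n_surfaces x parcels) plus the
#'   per-surface `alpha` fractions.
#' @export
sample_profiles <- function(intensity_field, geom, n_surfaces = 12,
                            thickness_mm = 2.5, area_out = NULL, area_in = NULL) {
  stopifnot(n_surfaces >= 2)
  depths <- intensity_field$depths
  vals <- intensity_field$values
  if (anyNA(vals[!is.na(geom$vertex_to_parcel), ])) {
    stop("missing depth samples for parcel vertices", call. = FALSE)
  }
  if (is.null(area_in)) area_in <- vertex_areas(geom$mesh)
  if (is.null(area_out)) {
    area_out <- area_in * (1 + thickness_mm / geom$radius)^2
  }
  v2p <- geom$vertex_to_parcel
  ok <- which(!is.na(v2p))
  p <- length(geom$parcel_id)
  alphas <- seq(0, 1, length.out = n_surfaces)
  out <- matrix(NA_real_, n_surfaces, p,
    dimnames = list(NULL, paste0("p", geom$parcel_id))
  )
  for (s in seq_len(n_surfaces)) {
    rho <- equivolumetric_rho(alphas[s], area_out[ok], area_in[ok])
    intens <- interp_rows(vals[ok, , drop = FALSE], depths, rho)
    out[s, ] <- as.numeric(rowsum(intens, v2p[ok]) / tabulate(v2p[ok], p))
  }
  structure(
    list(intensities = out, n_surfaces = n_surfaces, alpha = alphas),
    class = "profile_matrix"
  )
}

#' Microstructural profile covariance (MPC)
#'
#' For each subject, correlates parcel depth profiles across surfaces and
#' removes the shared dependence on the cortex-wide mean profile `c` by
#' partial correlation:
#' `MPC(i, j) = (r_ij - r_ic * r_jc) / sqrt((1 - r_ic^2) (1 - r_jc^2))`,
#' then averages over subjects (optionally after Fisher z-transform).
#' Diagonal is 1 by convention. Cells where a parcel profile is perfectly
#' correlated with the mean profile are undefined and returned NA.
#'
#' @param profiles A `profile_matrix`, a single depths x parcels matrix, or a
#'   list of per-subject ones.
#' @param fisher_z Average subject matrices on the Fisher z scale.
#' @return A `parcel_matrix` of kind `"mpc"`.
#' @export
mpc_matrix <- function(profiles, fisher_z = FALSE) {
  if (inherits(profiles, "profile_matrix")) profiles <- list(profiles$intensities)
  if (is.matrix(profiles)) profiles <- list(profiles)
  profiles <- lapply(profiles, function(x) {
    if (inherits(x, "profile_matrix")) x$intensities else as.matrix(x)
  })
  stopifnot(length(profiles) >= 1)
  if (nrow(profiles[[1]]) < 3) stop("need at least 3 surfaces", call. = FALSE)
  acc <- NULL
  for (prof in profiles) {
    r <- stats::cor(prof)
    cbar <- rowMeans(prof)
    ric <- as.numeric(stats::cor(prof, cbar))
    denom <- sqrt(pmax(0, (1 - ric^2)) %o% pmax(0, (1 - ric^2)))
    mpc <- (r - ric %o% ric) / denom
    mpc[!is.finite(mpc)] <- NA_real_
    mpc <- pmin(pmax(mpc, -1), 1)
    if (fisher_z) mpc <- atanh(pmin(pmax(mpc, -1 + 1e-12), 1 - 1e-12))
    acc <- if (is.null(acc)) mpc else acc + mpc
  }
  avg <- acc / length(profiles)
  if (fisher_z) avg <- tanh(avg)
  diag(avg) <- 1
  parcel_matrix(avg,
    kind = "mpc",
    parcel_ids = colnames(profiles[[1]]),
    meta = list(n_subjects = length(profiles), fisher_z = fisher_z)
  )
}
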