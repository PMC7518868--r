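pipeline_defaults <- function() {
  list(
    n_parcels = 100, mesh_resolution = 4,
    n_mz = 200, n_dz = 200, n_singleton = 100,
    h2_mean = 0.3, gradient_weights = c(1, 0.3), length_scale = 0.5,
    unique_variance = 0.3,
    trim_fraction = 0.10, covariate_preset = "covariance",
    keep_fraction = 0.10, alpha = 0.5, n_components = 10, n_bins = 10,
    n_rotations = 1000, n_perm = 1000,
    run_quantgen = FALSE, run_mpc = TRUE,
    seed = 1L, out_dir = "covgrad_run"
  )
}

validate_config <- function(config) {
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defs, config)
  with(cfg, {
    stopifnot(
      n_parcels >= 4, n_mz >= 0, n_dz >= 0, n_singleton >= 0,
      h2_mean > 0, h2_mean < 1,
      trim_fraction >= 0, trim_fraction < 0.5,
      alpha >= 0, alpha <= 1,
      n_components >= 1, n_bins >= 2, n_rotations >= 1, n_perm >= 1
    )
    if (keep_fraction <= 0 || keep_fraction > 1) {
      stop("keep_fraction must be in (0, 1]", call. = FALSE)
    }
  })
  cfg
}

child_seed <- function(seed, stage) {
  # per-stage derived seeds, reproducible and within 32-bit integer range
  offsets <- c(
    simulate = 1L, covariance = 2L, quantgen = 3L, gradients = 4L,
    spin = 5L, energy = 6L, mpc = 7L
  )
  as.integer((as.numeric(seed) %% 2000000) * 1000 + offsets[[stage]])
}

sidecar <- function(path, settings, seed) {
  jsonlite::write_json(
    list(
      settings = settings, seed = seed,
      package_version = as.character(utils::packageVersion("covgrad"))
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Generates geometry + ground truth + a twin cohort, then runs the enabled
#' stages in dependency order: covariate residualization and structural
#' covariance with a community test, optional pairwise AE genetic-correlation
#' fits, gradient decomposition (threshold, normalized-angle affinity,
#' diffusion embedding, binning), spatial inference (spin test of the first
#' gradient against the planted axis, dual-origin distance analysis), and
#' optional microstructural profile covariance with its own gradients.
#' Every artifact is written under `out_dir` with a JSON sidecar recording
#' settings and the per-stage derived seed (`seed * 1000 + stage index`),
#' so a rerun with the same config is byte-identical.
#'
#' @param config Named list of settings (see `pipeline_defaults`), or a path
#'   to a YAML file of the same; unknown keys are rejected.
#' @return Invisibly, a list with the main in-memory results and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n", file = log_path, append = TRUE)
  }
  cat("", file = log_path)

  # --- simulate ------------------------------------------------------------
  seed_sim <- child_seed(cfg$seed, "simulate")
  log_line("simulate: seed", seed_sim)
  geom <- make_sphere_parcellation(cfg$n_parcels, cfg$mesh_resolution)
  truth <- make_ground_truth(geom,
    h2_mean = cfg$h2_mean, weights = cfg$gradient_weights,
    length_scale = cfg$length_scale, unique_variance = cfg$unique_variance
  )
  cohort <- simulate_cohort(truth, cfg$n_mz, cfg$n_dz, cfg$n_singleton,
    seed = seed_sim
  )
  write_geometry(geom, file.path(out, "geometry"))
  write_cohort(
    cohort, file.path(out, "phenotypes.tsv"),
    file.path(out, "pedigree.csv")
  )
  sidecar(file.path(out, "phenotypes.tsv.json"), cfg[c(
    "n_parcels", "mesh_resolution", "n_mz", "n_dz", "n_singleton", "h2_mean"
  )], seed_sim)

  # --- covariance ----------------------------------------------------------
  seed_cov <- child_seed(cfg$seed, "covariance")
  log_line("covariance: seed", seed_cov)
  cohort <- qc_hemispheric_difference(cohort, geom)
  res <- residualize(cohort, preset = cfg$covariate_preset)
  sc <- structural_covariance(res, meta = list(covariates = cfg$covariate_preset))
  write_matrix(sc, file.path(out, "structural_covariance.tsv"))
  comm <- tryCatch(
    community_test(sc, geom$community, n_perm = cfg$n_perm, seed = seed_cov),
    error = function(e) {
      log_line("community test skipped:", conditionMessage(e))
      NULL
    }
  )
  if (!is.null(comm)) {
    utils::write.csv(comm$per_community, file.path(out, "community_test.csv"),
      row.names = FALSE
    )
  }

  # --- quantgen (optional: heavy) -----------------------------------------
  ae <- NULL
  if (isTRUE(cfg$run_quantgen)) {
    log_line("quantgen: fitting", ncol(res) * (ncol(res) - 1) / 2, "pairs")
    traits_g <- residualize(cohort, preset = "genetic")
    traits_g <- apply(traits_g, 2, inverse_normal_transform)
    ae <- genetic_correlation_matrix(traits_g, cohort$pheno)
    utils::write.table(ae$h2, file.path(out, "h2.tsv"),
      sep = "\t",
      row.names = FALSE, quote = FALSE
    )
    write_matrix(ae$rho_g, file.path(out, "rho_g.tsv"))
    write_matrix(ae$rho_e, file.path(out, "rho_e.tsv"))
  }

  # --- gradients -----------------------------------------------------------
  log_line("gradients: keep_fraction", cfg$keep_fraction, "alpha", cfg$alpha)
  grads <- covariance_gradients(sc,
    keep_fraction = cfg$keep_fraction,
    n_components = cfg$n_components, alpha = cfg$alpha,
    anchor = truth$g1_axis
  )
  grad_tab <- tibble::as_tibble(grads$coords, rownames = "parcel_id")
  utils::write.table(grad_tab, file.path(out, "gradients.tsv"),
    sep = "\t",
    row.names = FALSE, quote = FALSE
  )
  sidecar(
    file.path(out, "gradients.tsv.json"),
    c(cfg[c("keep_fraction", "alpha", "n_components")], list(
      eigenvalues = grads$eigenvalues,
      variance_explained = grads$variance_explained
    )),
    cfg$seed
  )
  bins <- bin_gradient(grads, sc, n_bins = min(cfg$n_bins, cfg$n_parcels))

  # --- spatial -------------------------------------------------------------
  seed_spin <- child_seed(cfg$seed, "spin")
  log_line("spatial: spin + dual origin, seed", seed_spin)
  spins <- spin_permutations(geom, cfg$n_rotations, seed = seed_spin)
  spin_g1 <- spin_test(grads$coords[, 1], truth$g1_axis, spins = spins)
  fields <- origin_distance_fields(geom)
  dual <- dual_origin_association(grads, fields, geom,
    n_rotations = cfg$n_rotations, seed = child_seed(cfg$seed, "energy"),
    spins = spins
  )
  jsonlite::write_json(
    list(
      g1_vs_planted_axis = spin_g1[c("r_observed", "p_spin", "n_rotations")],
      dual_origin = dual,
      seed = seed_spin
    ),
    file.path(out, "spatial_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  # --- mpc (optional) ------------------------------------------------------
  mpc <- NULL
  if (isTRUE(cfg$run_mpc)) {
    seed_mpc <- child_seed(cfg$seed, "mpc")
    log_line("mpc: seed", seed_mpc)
    field <- make_intensity_field(geom, seed = seed_mpc)
    prof <- sample_profiles(field, geom)
    mpc <- mpc_matrix(prof)
    write_matrix(mpc, file.path(out, "mpc.tsv"))
  }

  log_line("done")
  invisible(list(
    geom = geom, truth = truth, cohort = cohort, covariance = sc,
    community = comm, ae = ae, gradients = grads, bins = bins,
    spin_g1 = spin_g1, dual_origin = dual, mpc = mpc, out_dir = out
  ))
}

#' Gradient decomposition of a parcel matrix (threshold -> affinity -> embed)
#'
#' Convenience composition of [threshold_rows()],
#' [normalized_angle_affinity()] and [diffusion_embedding()] — the standard
#' route from a covariance-like matrix to its macroscale gradients.
#'
#' @param mat A `parcel_matrix` (covariance, genetic correlation, MPC, ...).
#' @param keep_fraction Row-threshold retention (default 0.10).
#' @param n_components,alpha,diffusion_time,anchor Passed to
#'   [diffusion_embedding()].
#' @return A `gradient_set` whose `source_kind` records the input kind.
#' @export
covariance_gradients <- function(mat, keep_fraction = 0.10, n_components = 10,
                                 alpha = 0.5, diffusion_time = 0, anchor = NULL) {
  sparse <- threshold_rows(mat, keep_fraction)
  aff <- normalized_angle_affinity(sparse)
  gs <- diffusion_embedding(aff,
    n_components = n_components, alpha = alpha,
    diffusion_time = diffusion_time, anchor = anchor
  )
  gs$source_kind <- if (inherits(mat, "parcel_matrix")) mat$kind else "matrix"
  gs$sparsity <- keep_fraction
  gs
}
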