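#' Planted genetic/environmental covariance structure for a parcellation
#'
#' Constructs the additive-genetic and unique-environmental parcel covariance
#' matrices that the cohort simulator draws from. Two planted axes are the
#' posterior-anterior (centroid y) and inferior-superior (centroid z)
#' spherical coordinates; each covariance is a weighted sum of
#' squared-exponential kernels on those axes plus a parcel-unique component,
#' scaled so every parcel has unit phenotypic variance and heritability
#' `h2_mean` (optionally graded along the first axis by `h2_range`).
#'
#' Both matrices are positive semi-definite by construction (sums of PSD
#' kernels plus a positive diagonal).
#'
#' @param geom A `parcel_geometry`.
#' @param h2_mean Planted mean heritability in (0,1).
#' @param weights Length-2 genetic kernel weights `c(w1, w2)` for the two
#'   axes; `w1 >> w2` plants a dominant first gradient.
#' @param length_scale Genetic kernel length scale on the unit-coordinate
#'   axis scale.
#' @param unique_variance Parcel-unique genetic variance (same relative
#'   units as the weights).
#' @param e_weights,e_length_scale,e_unique_variance Environmental analogues;
#'   the environmental structure is by default weaker and shorter-ranged.
#' @param h2_range Peak-to-peak linear variation of heritability along the
#'   first axis (0 = constant).
#' @param betas Covariate effects on thickness (mm units): per year of age
#'   and for sex.
#' @return A `ground_truth` list: `sigma_g`, `sigma_e`, `h2_true`,
#'   `rho_g_true`, `rho_e_true`, `g1_axis`, `g2_axis`, `betas`.
#' @export
make_ground_truth <- function(geom, h2_mean = 0.3,
                              weights = c(1, 0.3), length_scale = 0.5,
                              unique_variance = 0.3,
                              e_weights = c(0.5, 0.5), e_length_scale = 0.4,
                              e_unique_variance = 0.8,
                              h2_range = 0,
                              betas = c(age = -0.005, sex = 0.02)) {
  stopifnot(h2_mean > 0, h2_mean < 1, length_scale > 0, e_length_scale > 0)
  g1 <- geom$centroid[, 2]
  g2 <- geom$centroid[, 3]
  p <- length(g1)

  sq_exp <- function(g, ell) exp(-outer(g, g, "-")^2 / (2 * ell^2))
  corr_from_kernels <- function(w, ell, u) {
    k <- w[1] * sq_exp(g1, ell) + w[2] * sq_exp(g2, ell) + u * diag(p)
    k / (w[1] + w[2] + u)
  }
  rho_g <- corr_from_kernels(weights, length_scale, unique_variance)
  rho_e <- corr_from_kernels(e_weights, e_length_scale, e_unique_variance)

  h2 <- h2_mean + h2_range * (g1 - mean(g1)) / max(diff(range(g1)), 1e-12)
  h2 <- pmin(pmax(h2, 0.02), 0.98)

  dg <- sqrt(h2)
  de <- sqrt(1 - h2)
  sigma_g <- rho_g * tcrossprod(dg)
  sigma_e <- rho_e * tcrossprod(de)

  structure(
    list(
      sigma_g = sigma_g, sigma_e = sigma_e,
      h2_true = h2,
      rho_g_true = rho_g, rho_e_true = rho_e,
      g1_axis = g1, g2_axis = g2,
      betas = betas
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(
    "<ground_truth> ", length(x$h2_true), " parcels, mean h2 = ",
    round(mean(x$h2_true), 3), "\n",
    sep = ""
  )
  invisible(x)
}

mvn_draw <- function(n, chol_upper) {
  matrix(stats::rnorm(n * nrow(chol_upper)), n) %*% chol_upper
}

#' Simulate a twin cohort with planted covariance structure
#'
#' Draws additive-genetic parcel values per family — shared between
#' monozygotic co-twins, correlated 0.5 between dizygotic co-twins
#' (`a2 = a1/2 + sqrt(3)/2 * a_indep`) — plus independent environmental
#' values per subject, and assembles thickness as
#' `baseline + age*beta_age + sex*beta_sex + site effect +
#' thickness_scale * (a + e)`.
#'
#' Twins share family, age, and site; monozygotic co-twins share sex.
#' Age is uniform on `age_range` years, sex Bernoulli(1/2), site uniform
#' over `n_sites` with a small site intercept.
#'
#' @param truth A `ground_truth`.
#' @param n_mz,n_dz Numbers of MZ and DZ twin families (2 members each).
#' @param n_singleton Number of unpaired subjects.
#' @param seed Integer seed; all randomness flows through it.
#' @param baseline Mean thickness (mm).
#' @param thickness_scale Standard-deviation scale (mm) applied to the
#'   unit-variance genetic + environmental deviations.
#' @param age_range Age bounds (years).
#' @param n_sites Number of acquisition sites.
#' @param site_sd Standard deviation of site intercepts (mm).
#' @return A `twin_cohort`: `pheno` tibble (subject_id, family_id, zygosity,
#'   age, sex, site) and `thickness` matrix (subjects x parcels).
#' @export
simulate_cohort <- function(truth, n_mz, n_dz, n_singleton = 0, seed = 1L,
                            baseline = 2.5, thickness_scale = 0.25,
                            age_range = c(22, 37), n_sites = 1,
                            site_sd = 0.01) {
  n_subj <- 2 * n_mz + 2 * n_dz + n_singleton
  if (n_subj == 0) stop("empty cohort: no families or singletons requested", call. = FALSE)
  set.seed(seed)
  p <- ncol(truth$sigma_g)
  jit <- 1e-8 * diag(p)
  cg <- chol(truth$sigma_g + jit)
  ce <- chol(truth$sigma_e + jit)

  n_fam <- n_mz + n_dz
  zyg_fam <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  fam_id <- c(rep(seq_len(n_fam), each = 2), seq_len(n_singleton) + n_fam)
  zyg <- c(rep(zyg_fam, each = 2), rep("singleton", n_singleton))
  twin_no <- c(rep(1:2, n_fam), rep(1L, n_singleton))

  # additive-genetic values
  a <- matrix(0, n_subj, p)
  if (n_fam > 0) {
    a1 <- mvn_draw(n_fam, cg)
    a_ind <- mvn_draw(n_fam, cg)
    is_mz_fam <- zyg_fam == "MZ"
    a2 <- a1
    a2[!is_mz_fam, ] <- 0.5 * a1[!is_mz_fam, , drop = FALSE] +
      (sqrt(3) / 2) * a_ind[!is_mz_fam, , drop = FALSE]
    a[which(twin_no == 1 & zyg != "singleton"), ] <- a1
    a[which(twin_no == 2), ] <- a2
  }
  if (n_singleton > 0) {
    a[zyg == "singleton", ] <- mvn_draw(n_singleton, cg)
  }
  e <- mvn_draw(n_subj, ce)

  # covariates: per family for twins, per subject for singletons
  age_fam <- stats::runif(n_fam + n_singleton, age_range[1], age_range[2])
  site_fam <- sample.int(n_sites, n_fam + n_singleton, replace = TRUE)
  age <- age_fam[fam_id]
  site <- site_fam[fam_id]
  sex <- stats::rbinom(n_subj, 1, 0.5)
  if (n_fam > 0) {
    i1 <- which(twin_no == 1 & zyg == "MZ")
    sex[i1 + 1L] <- sex[i1]
  }
  site_eff <- if (n_sites > 1) stats::rnorm(n_sites, 0, site_sd) else 0

  thick <- baseline +
    age * truth$betas[["age"]] + sex * truth$betas[["sex"]] +
    (if (n_sites > 1) site_eff[site] else 0) +
    thickness_scale * (a + e)
  colnames(thick) <- paste0("p", seq_len(p))

  pheno <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n_subj)),
    family_id = sprintf("F%04d", fam_id),
    zygosity = zyg,
    age = age,
    sex = sex,
    site = site
  )
  rownames(thick) <- pheno$subject_id
  structure(list(pheno = pheno, thickness = thick), class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  z <- table(x$pheno$zygosity)
  cat(
    "<twin_cohort> ", nrow(x$thickness), " subjects x ", ncol(x$thickness),
    " parcels (", paste(names(z), z, sep = "=", collapse = ", "), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Cohort phenotype table
#' @param x A `twin_cohort`.
#' @param ... Unused.
#' @return The phenotype tibble (one row per subject).
#' @export
tidy.twin_cohort <- function(x, ...) x$pheno

#' Thickness matrix of a cohort
#' @param cohort A `twin_cohort`.
#' @return Subjects x parcels matrix (mm).
#' @export
thickness_matrix <- function(cohort) cohort$thickness
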