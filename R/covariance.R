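#' Aggregate vertex values to parcels by trimmed mean
#'
#' For each parcel, drops the `floor(trim_fraction * m)` smallest and largest
#' of its `m` vertex values (stable order for ties) and averages the rest.
#' Medial-wall vertices are ignored.
#'
#' @param vertex_values Numeric vector, one value per mesh vertex.
#' @param geom A `parcel_geometry`.
#' @param trim_fraction Proportion trimmed from each tail, in [0, 0.5).
#' @return Named numeric vector, one value per parcel.
#' @export
aggregate_parcels <- function(vertex_values, geom, trim_fraction = 0.10) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  v2p <- geom$vertex_to_parcel
  if (length(vertex_values) != length(v2p)) {
    stop("vertex_values length must match mesh vertex count", call. = FALSE)
  }
  p <- length(geom$parcel_id)
  out <- numeric(p)
  for (k in seq_len(p)) {
    vals <- vertex_values[which(v2p == k)]
    m <- length(vals)
    if (m == 0) stop("parcel ", k, " has zero vertices", call. = FALSE)
    drop_n <- floor(trim_fraction * m)
    vals <- sort(vals, method = "radix")
    if (drop_n > 0) vals <- vals[(drop_n + 1):(m - drop_n)]
    out[k] <- mean(vals)
  }
  names(out) <- paste0("p", geom$parcel_id)
  out
}

#' Build a covariate design matrix for a cohort
#'
#' Presets: `"covariance"` = age + sex + global thickness (the structural
#' covariance control set); `"genetic"` adds age^2 and age x sex (the set used
#' upstream of heritability fits). A `site` factor is appended when the
#' cohort has more than one site.
#'
#' @param cohort A `twin_cohort`.
#' @param preset `"covariance"` or `"genetic"`.
#' @param include_site Add site as a categorical covariate.
#' @return Design matrix (with intercept).
#' @keywords internal
covariate_design <- function(cohort, preset = c("covariance", "genetic"),
                             include_site = NULL) {
  preset <- match.arg(preset)
  ph <- cohort$pheno
  global <- rowMeans(cohort$thickness)
  df <- data.frame(age = ph$age, sex = ph$sex, global = global)
  form <- if (preset == "genetic") {
    ~ age + sex + global + I(age^2) + age:sex
  } else {
    ~ age + sex + global
  }
  if (is.null(include_site)) include_site <- length(unique(ph$site)) > 1
  if (include_site) {
    df$site <- factor(ph$site)
    form <- stats::update(form, ~ . + site)
  }
  stats::model.matrix(form, df)
}

#' Residualize parcel thickness against covariates
#'
#' Ordinary least-squares residuals, per parcel, against the declared terms
#' plus intercept. Global thickness is the per-subject mean across parcels.
#'
#' @param cohort A `twin_cohort`, or a subjects x parcels matrix if `design`
#'   is supplied.
#' @param preset Covariate preset (see [covariate_design()]).
#' @param design Optional explicit design matrix (overrides `preset`).
#' @param include_site Add site as categorical covariate (default: only when
#'   more than one site is present).
#' @return Residual matrix (subjects x parcels) with a `design` attribute.
#' @export
residualize <- function(cohort, preset = c("covariance", "genetic"),
                        design = NULL, include_site = NULL) {
  if (inherits(cohort, "twin_cohort")) {
    y <- cohort$thickness
    if (is.null(design)) design <- covariate_design(cohort, preset, include_site)
  } else {
    y <- as.matrix(cohort)
    if (is.null(design)) stop("supply a design matrix when not passing a twin_cohort", call. = FALSE)
  }
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    bad <- colnames(design)[qrx$pivot[(qrx$rank + 1):ncol(design)]]
    stop("design matrix rank deficient; collinear terms: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  res <- qr.resid(qrx, y)
  dimnames(res) <- dimnames(y)
  attr(res, "design") <- design
  res
}

#' Structural covariance matrix
#'
#' Pearson correlation across subjects for every parcel pair, computed on
#' covariate-residualized thickness.
#'
#' @param residuals Subjects x parcels matrix (from [residualize()]).
#' @param meta Extra provenance fields stored on the result.
#' @return A `parcel_matrix` of kind `"covariance"` with unit diagonal.
#' @export
structural_covariance <- function(residuals, meta = list()) {
  x <- as.matrix(residuals)
  if (nrow(x) < 3) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance parcel(s): ",
      paste(colnames(x)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  r <- stats::cor(x)
  diag(r) <- 1
  parcel_matrix(r,
    kind = "covariance",
    meta = c(list(n_subjects = nrow(x)), meta)
  )
}

#' Exclude subjects with large hemispheric thickness asymmetry
#'
#' Removes subjects whose absolute difference between mean left- and mean
#' right-hemisphere thickness exceeds `threshold_cm` (default 0.2 cm).
#' Thickness is in mm; the threshold is converted internally.
#'
#' @param cohort A `twin_cohort`.
#' @param geom A `parcel_geometry` (for hemisphere labels).
#' @param threshold_cm Exclusion threshold in cm.
#' @return The cohort restricted to retained subjects, with attribute
#'   `excluded` listing dropped subject ids.
#' @export
qc_hemispheric_difference <- function(cohort, geom, threshold_cm = 0.2) {
  hemi <- geom$hemisphere
  if (length(unique(hemi)) < 2) stop("both hemispheres required", call. = FALSE)
  left <- rowMeans(cohort$thickness[, hemi == "L", drop = FALSE])
  right <- rowMeans(cohort$thickness[, hemi == "R", drop = FALSE])
  keep <- abs(left - right) <= threshold_cm * 10
  out <- cohort
  out$pheno <- cohort$pheno[keep, , drop = FALSE]
  out$thickness <- cohort$thickness[keep, , drop = FALSE]
  attr(out, "excluded") <- cohort$pheno$subject_id[!keep]
  out
}

community_within_means <- function(vals, communities, comms) {
  vapply(comms, function(cm) {
    idx <- which(communities == cm)
    sub <- vals[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
}

#' Community-level covariance test with a permutation null
#'
#' Summarises mean within- and between-community values of a symmetric
#' parcel matrix and tests, per community, whether its mean within-community
#' value exceeds what parcel-label permutation (preserving community sizes)
#' produces. One-sided p-values `(1 + #{null >= obs}) / (n_perm + 1)`;
#' Benjamini-Hochberg q-values.
#'
#' Communities with fewer than 2 parcels are excluded with a warning.
#'
#' @param mat A `parcel_matrix` (or plain symmetric matrix).
#' @param communities Integer/character community label per parcel.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed.
#' @return A `community_summary`: tibble `per_community` (community, n_parcels,
#'   mean, p_value, q_value) plus `within_mean` and `between_mean` scalars.
#' @export
community_test <- function(mat, communities, n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  vals <- pm_values(mat)
  p <- nrow(vals)
  stopifnot(length(communities) == p)
  sizes <- table(communities)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning(
      "excluding communities with < 2 parcels: ",
      paste(small, collapse = ", ")
    )
  }
  comms <- names(sizes)[sizes >= 2]
  if (length(comms) < 2) stop("need at least 2 communities with >= 2 parcels", call. = FALSE)

  same <- outer(communities, communities, "==")
  ut <- upper.tri(vals)
  within_mean <- mean(vals[ut & same])
  between_mean <- mean(vals[ut & !same])

  obs <- community_within_means(vals, communities, comms)
  set.seed(seed)
  exceed <- numeric(length(comms))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(p)
    null_b <- community_within_means(vals, communities[perm], comms)
    exceed <- exceed + (null_b >= obs)
  }
  pval <- (1 + exceed) / (n_perm + 1)
  qval <- stats::p.adjust(pval, method = "BH")
  structure(
    list(
      per_community = tibble::tibble(
        community = comms,
        n_parcels = as.integer(sizes[comms]),
        mean = obs,
        p_value = pval,
        q_value = qval
      ),
      within_mean = within_mean,
      between_mean = between_mean,
      n_perm = n_perm,
      seed = seed
    ),
    class = "community_summary"
  )
}

#' @export
print.community_summary <- function(x, ...) {
  cat(
    "<community_summary> within = ", round(x$within_mean, 4),
    ", between = ", round(x$between_mean, 4), ", ",
    sum(x$per_community$q_value < 0.05), "/", nrow(x$per_community),
    " communities q < 0.05\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.community_summary <- function(x, ...) x$per_community

#' @export
glance.community_summary <- function(x, ...) {
  tibble::tibble(
    within_mean = x$within_mean,
    between_mean = x$between_mean,
    n_communities = nrow(x$per_community),
    n_significant = sum(x$per_community$q_value < 0.05),
    n_perm = x$n_perm
  )
}
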