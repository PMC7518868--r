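#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles of their Blom plotting positions,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. Monotone
#' with the input; NA values are preserved.
#'
#' @param values Numeric vector with at least 3 distinct non-missing values.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(x)) == 1) stop("all values equal; ranks undefined", call. = FALSE)
  n <- length(x)
  out <- values
  out[ok] <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out
}

# Row-index structure for twin pairs and singletons.
# Pairs are (first, second) member per MZ/DZ family; errors on malformed
# families.
pair_index <- function(pedigree) {
  ped <- if (inherits(pedigree, "twin_cohort")) pedigree$pheno else pedigree
  stopifnot(all(c("family_id", "zygosity") %in% names(ped)))
  idx <- list()
  for (z in c("MZ", "DZ")) {
    rows <- which(ped$zygosity == z)
    if (length(rows) == 0) {
      idx[[z]] <- matrix(integer(0), 0, 2)
      next
    }
    fams <- split(rows, ped$family_id[rows])
    bad <- names(fams)[lengths(fams) != 2]
    if (length(bad) > 0) {
      stop(
        z, " families without exactly 2 members: ",
        paste(utils::head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
    idx[[z]] <- do.call(rbind, fams)
  }
  idx$singleton <- which(ped$zygosity == "singleton")
  idx
}

uni_profile_nll <- function(h2, stats_list) {
  # profile negative log-likelihood over h2; scale solved analytically
  tr_sum <- 0
  logdet_sum <- 0
  for (k in c("MZ", "DZ")) {
    st <- stats_list[[k]]
    if (st$n == 0) next
    r <- if (k == "MZ") h2 else 0.5 * h2
    det_c <- 1 - r^2
    tr_sum <- tr_sum + (st$s11 + st$s22 - 2 * r * st$s12) / det_c
    logdet_sum <- logdet_sum + st$n * log(det_c)
  }
  tr_sum <- tr_sum + stats_list$singleton$ss
  n_tot <- stats_list$n_obs
  sigma2 <- tr_sum / n_tot
  0.5 * (n_tot * log(2 * pi * sigma2) + logdet_sum + n_tot)
}

#' Univariate AE (G+E) twin model by maximum likelihood
#'
#' Fits heritability `h2 = sigma2_g / sigma2_p` by maximizing the Gaussian
#' pair likelihood in which co-twin covariance is `h2 * sigma2_p` for MZ and
#' `0.5 * h2 * sigma2_p` for DZ pairs; singletons contribute to the variance
#' only. The phenotypic scale is profiled out analytically, leaving a
#' one-dimensional bounded optimization over `h2` (grid-bracketed, then
#' refined), so the fit is deterministic. The trait is mean-centered
#' internally and should be residualized / inverse-normal transformed
#' upstream.
#'
#' @param trait Per-subject numeric vector.
#' @param pedigree Tibble/data.frame with `family_id` and `zygosity`
#'   (`"MZ"`, `"DZ"`, `"singleton"`), rows aligned with `trait`; or a
#'   `twin_cohort`.
#' @return List with `h2`, `sigma_p2`, `loglik`, pair counts, and
#'   `convergence` (0 = clean).
#' @export
fit_univariate_ae <- function(trait, pedigree) {
  idx <- pair_index(pedigree)
  n_mz <- nrow(idx$MZ)
  n_dz <- nrow(idx$DZ)
  if (n_mz + n_dz == 0) stop("no twin pairs in pedigree", call. = FALSE)
  y <- trait - mean(trait, na.rm = TRUE)
  st <- list(n_obs = 2 * n_mz + 2 * n_dz + length(idx$singleton))
  for (k in c("MZ", "DZ")) {
    m <- idx[[k]]
    y1 <- y[m[, 1]]
    y2 <- y[m[, 2]]
    st[[k]] <- list(
      n = nrow(m), s11 = sum(y1^2), s22 = sum(y2^2), s12 = sum(y1 * y2)
    )
  }
  st$singleton <- list(ss = sum(y[idx$singleton]^2))

  grid <- seq(0, 1, by = 0.05)
  nll_grid <- vapply(grid, uni_profile_nll, numeric(1), stats_list = st)
  i0 <- which.min(nll_grid)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(uni_profile_nll, c(lo, hi), stats_list = st, tol = 1e-9)
  h2 <- opt$minimum
  cands <- c(h2, 0, 1)
  nlls <- vapply(cands, uni_profile_nll, numeric(1), stats_list = st)
  h2 <- cands[which.min(nlls)]
  nll <- min(nlls)

  # recover the profiled scale at the optimum
  tr_sum <- st$singleton$ss
  for (k in c("MZ", "DZ")) {
    r <- if (k == "MZ") h2 else 0.5 * h2
    tr_sum <- tr_sum + (st[[k]]$s11 + st[[k]]$s22 - 2 * r * st[[k]]$s12) / (1 - r^2)
  }
  list(
    h2 = h2, sigma_p2 = tr_sum / st$n_obs, loglik = -nll,
    n_mz = n_mz, n_dz = n_dz, n_singleton = length(idx$singleton),
    convergence = 0L
  )
}

biv_sigma <- function(par, c_twin) {
  h2i <- par[1]; h2j <- par[2]; rg <- par[3]; re <- par[4]
  si2 <- exp(par[5]); sj2 <- exp(par[6])
  gi <- h2i * si2; gj <- h2j * sj2
  ei <- (1 - h2i) * si2; ej <- (1 - h2j) * sj2
  gij <- rg * sqrt(gi * gj)
  eij <- re * sqrt(ei * ej)
  w <- matrix(c(gi + ei, gij + eij, gij + eij, gj + ej), 2)
  g <- matrix(c(gi, gij, gij, gj), 2)
  rbind(cbind(w, c_twin * g), cbind(c_twin * g, w))
}

biv_nll <- function(par, suff) {
  val <- 0
  for (k in c("MZ", "DZ")) {
    s <- suff[[k]]
    if (s$n == 0) next
    sig <- biv_sigma(par, if (k == "MZ") 1 else 0.5)
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    val <- val + s$n * 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * s$S)
  }
  if (suff$singleton$n > 0) {
    sig <- biv_sigma(par, 0)[1:2, 1:2]
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    val <- val + suff$singleton$n * 2 * sum(log(diag(ch))) +
      sum(chol2inv(ch) * suff$singleton$S)
  }
  0.5 * (val + suff$n_obs * log(2 * pi))
}

biv_suff <- function(yi, yj, idx) {
  suff <- list()
  n_obs <- 0
  for (k in c("MZ", "DZ")) {
    m <- idx[[k]]
    if (nrow(m) == 0) {
      suff[[k]] <- list(n = 0L, S = NULL)
      next
    }
    y4 <- cbind(yi[m[, 1]], yj[m[, 1]], yi[m[, 2]], yj[m[, 2]])
    suff[[k]] <- list(n = nrow(m), S = crossprod(y4))
    n_obs <- n_obs + 2 * nrow(m)
  }
  sg <- idx$singleton
  if (length(sg) > 0) {
    y2 <- cbind(yi[sg], yj[sg])
    suff$singleton <- list(n = length(sg), S = crossprod(y2))
    n_obs <- n_obs + length(sg)
  } else {
    suff$singleton <- list(n = 0L, S = NULL)
  }
  # observation count in trait units: 2 traits per subject
  suff$n_obs <- 2 * n_obs
  suff
}

biv_moment_start <- function(suff) {
  safe_cor <- function(sxy, sxx, syy) sxy / sqrt(pmax(sxx * syy, 1e-12))
  rmz_i <- rdz_i <- rmz_j <- rdz_j <- 0
  cg_cross <- 0
  if (suff$MZ$n > 0) {
    S <- suff$MZ$S
    rmz_i <- safe_cor(S[1, 3], S[1, 1], S[3, 3])
    rmz_j <- safe_cor(S[2, 4], S[2, 2], S[4, 4])
    cmz <- (S[1, 4] + S[2, 3]) / (2 * suff$MZ$n)
  } else {
    cmz <- 0
  }
  if (suff$DZ$n > 0) {
    S <- suff$DZ$S
    rdz_i <- safe_cor(S[1, 3], S[1, 1], S[3, 3])
    rdz_j <- safe_cor(S[2, 4], S[2, 2], S[4, 4])
    cdz <- (S[1, 4] + S[2, 3]) / (2 * suff$DZ$n)
  } else {
    cdz <- 0
  }
  clamp <- function(x, a, b) pmin(pmax(x, a), b)
  h2i <- clamp(2 * (rmz_i - rdz_i), 0.05, 0.95)
  h2j <- clamp(2 * (rmz_j - rdz_j), 0.05, 0.95)
  covg <- 2 * (cmz - cdz)
  rg <- clamp(covg / sqrt(h2i * h2j), -0.9, 0.9)
  # within-person cross-trait covariance over all groups (standardized traits)
  num <- 0
  den <- 0
  for (k in c("MZ", "DZ")) {
    if (suff[[k]]$n > 0) {
      S <- suff[[k]]$S
      num <- num + S[1, 2] + S[3, 4]
      den <- den + 2 * suff[[k]]$n
    }
  }
  if (suff$singleton$n > 0) {
    num <- num + suff$singleton$S[1, 2]
    den <- den + suff$singleton$n
  }
  covp <- num / den
  re <- clamp((covp - covg) / sqrt((1 - h2i) * (1 - h2j)), -0.9, 0.9)
  c(h2i, h2j, rg, re, 0, 0)
}

run_biv_optim <- function(start, suff, fixed = NULL) {
  # fixed: list(index, value) to constrain one correlation (restricted model)
  free <- setdiff(seq_len(6), fixed$index)
  lower <- c(0, 0, -0.999, -0.999, -5, -5)
  upper <- c(1, 1, 0.999, 0.999, 5, 5)
  fn <- function(pf) {
    par <- numeric(6)
    par[free] <- pf
    if (!is.null(fixed)) par[fixed$index] <- fixed$value
    biv_nll(par, suff)
  }
  opt <- stats::optim(start[free], fn,
    method = "L-BFGS-B",
    lower = lower[free], upper = upper[free],
    control = list(maxit = 400)
  )
  par <- numeric(6)
  par[free] <- opt$par
  if (!is.null(fixed)) par[fixed$index] <- fixed$value
  list(par = par, nll = opt$value, convergence = opt$convergence)
}

#' Bivariate AE twin model: genetic and environmental correlation
#'
#' Maximizes the 4-variate Gaussian likelihood of twin-pair trait vectors
#' `(y_i1, y_j1, y_i2, y_j2)` over `(h2_i, h2_j, rho_g, rho_e)` and two trait
#' scales, with cross-twin genetic sharing 1 (MZ) and 0.5 (DZ); singletons
#' contribute their within-person 2x2 block. Significance of each
#' correlation comes from likelihood-ratio tests of the `rho_g = 0` and
#' `rho_e = 0` restricted models against the full model (chi-square, 1 df).
#' The implied phenotypic correlation is
#' `rho_p = rho_g * sqrt(h2_i h2_j) + rho_e * sqrt((1 - h2_i)(1 - h2_j))`.
#'
#' Traits are standardized internally; estimates are invariant to affine
#' rescaling. When a heritability lands on the 0 boundary the genetic
#' correlation is undefined and reported as NA with `boundary = TRUE`.
#'
#' @param trait_i,trait_j Per-subject numeric vectors.
#' @param pedigree As in [fit_univariate_ae()].
#' @param compute_lrt Fit the restricted models and report LRT p-values.
#' @param multi_start Add fixed heritability starts (0.1/0.5/0.9) to the
#'   moment-based start.
#' @return List with `h2_i`, `h2_j`, `rho_g`, `rho_e`, `rho_p`, `loglik`,
#'   `p_rho_g`, `p_rho_e`, `boundary`, `convergence`.
#' @export
fit_bivariate_ae <- function(trait_i, trait_j, pedigree,
                             compute_lrt = TRUE, multi_start = TRUE) {
  idx <- pair_index(pedigree)
  if (nrow(idx$MZ) + nrow(idx$DZ) == 0) stop("no twin pairs in pedigree", call. = FALSE)
  yi <- as.numeric(scale(trait_i))
  yj <- as.numeric(scale(trait_j))
  suff <- biv_suff(yi, yj, idx)

  start0 <- biv_moment_start(suff)
  starts <- list(start0)
  if (multi_start) {
    for (h in c(0.1, 0.5, 0.9)) {
      starts <- c(starts, list(c(h, h, start0[3], start0[4], 0, 0)))
    }
  }
  fits <- lapply(starts, run_biv_optim, suff = suff)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "nll"))]]
  par <- best$par
  ll_full <- -best$nll

  p_rho_g <- p_rho_e <- NA_real_
  if (compute_lrt) {
    lrt_one <- function(index) {
      r0 <- run_biv_optim(par, suff, fixed = list(index = index, value = 0))
      if (-r0$nll > ll_full + 1e-6) {
        # restricted beat full: restart full model from restricted solution
        refit <- run_biv_optim(r0$par, suff)
        if (-refit$nll > ll_full) {
          best <<- refit
          par <<- refit$par
          ll_full <<- -refit$nll
        }
      }
      stat <- max(0, 2 * (ll_full - (-r0$nll)))
      stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
    p_rho_g <- lrt_one(3)
    p_rho_e <- lrt_one(4)
  }

  boundary <- par[1] < 1e-4 || par[2] < 1e-4
  rho_g <- if (boundary) NA_real_ else par[3]
  rho_p <- par[3] * sqrt(par[1] * par[2]) +
    par[4] * sqrt((1 - par[1]) * (1 - par[2]))
  list(
    h2_i = par[1], h2_j = par[2],
    rho_g = rho_g, rho_e = par[4], rho_p = rho_p,
    loglik = ll_full, p_rho_g = p_rho_g, p_rho_e = p_rho_e,
    boundary = boundary, convergence = best$convergence
  )
}

#' Decompose a phenotypic correlation into genetic and environmental paths
#'
#' `rho_ph_g = sqrt(h2_i) * rho_g * sqrt(h2_j)` is the genetic path,
#' `rho_ph_e = sqrt(1 - h2_i) * rho_e * sqrt(1 - h2_j)` the environmental
#' path; their sum is the phenotypic correlation and `prop_genetic` is the
#' genetic share `rho_ph_g / rho_p`. Vectorized; `prop_genetic` is NA where
#' `rho_p` is 0.
#'
#' @param h2_i,h2_j Heritabilities in [0,1].
#' @param rho_g,rho_e Genetic and environmental correlations in [-1,1].
#' @return Tibble with `rho_ph_g`, `rho_ph_e`, `rho_p`, `prop_genetic`.
#' @export
decompose_phenotypic <- function(h2_i, h2_j, rho_g, rho_e) {
  stopifnot(all(h2_i >= 0 & h2_i <= 1, na.rm = TRUE))
  stopifnot(all(h2_j >= 0 & h2_j <= 1, na.rm = TRUE))
  rho_ph_g <- sqrt(h2_i) * rho_g * sqrt(h2_j)
  rho_ph_e <- sqrt(1 - h2_i) * rho_e * sqrt(1 - h2_j)
  rho_p <- rho_ph_g + rho_ph_e
  prop <- ifelse(rho_p == 0, NA_real_, rho_ph_g / rho_p)
  tibble::tibble(
    rho_ph_g = rho_ph_g, rho_ph_e = rho_ph_e,
    rho_p = rho_p, prop_genetic = prop
  )
}

#' Genetic/environmental correlation matrices over all parcel pairs
#'
#' Runs [fit_univariate_ae()] per parcel and [fit_bivariate_ae()] over all
#' `p(p-1)/2` parcel pairs of a prepared (residualized + inverse-normal
#' transformed) trait matrix, and assembles the genetic, environmental, and
#' implied phenotypic correlation matrices with unit diagonals. Each pair is
#' fitted independently, so results do not depend on pair order. Failed or
#' boundary pairs are recorded and left missing.
#'
#' @param traits Subjects x parcels matrix, already residualized and
#'   transformed.
#' @param pedigree As in [fit_univariate_ae()].
#' @param compute_lrt Also assemble LRT p-value matrices (slower).
#' @param multi_start Passed to [fit_bivariate_ae()].
#' @param progress Print a dot every 200 pairs.
#' @return An `ae_fit`: `h2` (per-parcel tibble), `rho_g`, `rho_e`, `rho_p`
#'   (`parcel_matrix` objects), optional `p_rho_g`/`p_rho_e`, `n_failed`.
#' @export
genetic_correlation_matrix <- function(traits, pedigree, compute_lrt = FALSE,
                                       multi_start = TRUE, progress = FALSE) {
  y <- as.matrix(traits)
  p <- ncol(y)
  ids <- colnames(y)
  if (is.null(ids)) ids <- paste0("p", seq_len(p))
  uni <- lapply(seq_len(p), function(k) fit_univariate_ae(y[, k], pedigree))
  h2_tab <- tibble::tibble(
    parcel_id = ids,
    h2 = vapply(uni, `[[`, numeric(1), "h2"),
    sigma_p2 = vapply(uni, `[[`, numeric(1), "sigma_p2"),
    loglik = vapply(uni, `[[`, numeric(1), "loglik")
  )
  rho_g <- rho_e <- rho_p <- diag(p)
  pg <- pe <- matrix(NA_real_, p, p)
  n_failed <- 0L
  done <- 0L
  pair_rows <- vector("list", p * (p - 1) / 2)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      fit <- tryCatch(
        fit_bivariate_ae(y[, i], y[, j], pedigree,
          compute_lrt = compute_lrt, multi_start = multi_start
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || fit$boundary) {
        n_failed <- n_failed + 1L
        rho_g[i, j] <- rho_g[j, i] <- NA_real_
        rho_e[i, j] <- rho_e[j, i] <- if (is.null(fit)) NA_real_ else fit$rho_e
        rho_p[i, j] <- rho_p[j, i] <- if (is.null(fit)) NA_real_ else fit$rho_p
      } else {
        rho_g[i, j] <- rho_g[j, i] <- fit$rho_g
        rho_e[i, j] <- rho_e[j, i] <- fit$rho_e
        rho_p[i, j] <- rho_p[j, i] <- fit$rho_p
        pg[i, j] <- pg[j, i] <- fit$p_rho_g
        pe[i, j] <- pe[j, i] <- fit$p_rho_e
      }
      done <- done + 1L
      if (!is.null(fit)) {
        pair_rows[[done]] <- tibble::tibble(
          parcel_i = ids[i], parcel_j = ids[j],
          h2_i = fit$h2_i, h2_j = fit$h2_j,
          rho_g = fit$rho_g, rho_e = fit$rho_e, rho_p = fit$rho_p,
          boundary = fit$boundary
        )
      }
      if (progress && done %% 200 == 0) cat(".")
    }
  }
  if (progress) cat("\n")
  dimnames(rho_g) <- dimnames(rho_e) <- dimnames(rho_p) <- list(ids, ids)
  meta <- list(
    n_subjects = nrow(y),
    n_pairs_fitted = done, n_failed = n_failed
  )
  structure(
    list(
      h2 = h2_tab,
      pairs = dplyr::bind_rows(pair_rows),
      rho_g = parcel_matrix(rho_g, "genetic_correlation", ids, meta),
      rho_e = parcel_matrix(rho_e, "environmental_correlation", ids, meta),
      rho_p = parcel_matrix(rho_p, "phenotypic_correlation", ids, meta),
      p_rho_g = if (compute_lrt) pg else NULL,
      p_rho_e = if (compute_lrt) pe else NULL,
      n_failed = n_failed
    ),
    class = "ae_fit"
  )
}

#' @export
print.ae_fit <- function(x, ...) {
  cat(
    "<ae_fit> ", nrow(x$h2), " parcels, mean h2 = ",
    round(mean(x$h2$h2), 3), ", ", x$n_failed, " failed pair(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Pairwise AE estimates in long form
#'
#' @param x An `ae_fit`.
#' @param ... Unused.
#' @return Tibble: parcel_i, parcel_j, per-pair h2 and correlation
#'   estimates, and the genetic decomposition from
#'   [decompose_phenotypic()].
#' @export
tidy.ae_fit <- function(x, ...) {
  base <- x$pairs
  dec <- decompose_phenotypic(base$h2_i, base$h2_j, base$rho_g, base$rho_e)
  dplyr::bind_cols(base, dec[c("rho_ph_g", "rho_ph_e", "prop_genetic")])
}

#' @export
glance.ae_fit <- function(x, ...) {
  g <- x$rho_g$values[upper.tri(x$rho_g$values)]
  tibble::tibble(
    n_parcels = nrow(x$h2),
    mean_h2 = mean(x$h2$h2),
    sd_h2 = stats::sd(x$h2$h2),
    mean_rho_g = mean(g, na.rm = TRUE),
    n_failed = x$n_failed
  )
}
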