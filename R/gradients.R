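#' Row-wise sparsification of a parcel matrix
#'
#' Per row, keeps the diagonal plus the top `floor(keep_fraction * (p - 1))`
#' off-diagonal entries by signed value and zeroes the rest — the row-wise
#' 90% cutoff of the gradient-mapping literature when `keep_fraction = 0.10`.
#' Ties at the cutoff are broken by column index (stable order). The result
#' is generally asymmetric.
#'
#' @param mat A `parcel_matrix` or symmetric numeric matrix.
#' @param keep_fraction Fraction of off-diagonal entries kept per row,
#'   in (0, 1].
#' @return Plain numeric matrix of thresholded rows.
#' @export
threshold_rows <- function(mat, keep_fraction = 0.10) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  x <- pm_values(mat)
  p <- nrow(x)
  k <- floor(keep_fraction * (p - 1))
  out <- matrix(0, p, p, dimnames = dimnames(x))
  diag(out) <- diag(x)
  if (k == 0) return(out)
  for (i in seq_len(p)) {
    row <- x[i, ]
    row[i] <- -Inf
    keep <- order(row, decreasing = TRUE)[seq_len(k)]
    out[i, keep] <- x[i, keep]
  }
  out
}

#' Normalized-angle affinity between connectivity rows
#'
#' `affinity(i, j) = 1 - acos(cosine(row_i, row_j)) / pi`: 1 for identical
#' directions, 0.5 for orthogonal rows, 0 for anti-parallel rows. Symmetric
#' with unit diagonal; entries in [0, 1] by construction.
#'
#' @param sparse_mat Matrix of (typically row-thresholded) connectivity rows.
#' @return A `parcel_matrix` of kind `"affinity"`.
#' @export
normalized_angle_affinity <- function(sparse_mat) {
  x <- pm_values(sparse_mat)
  norms <- sqrt(rowSums(x^2))
  zero <- which(norms == 0)
  if (length(zero) > 0) {
    stop("all-zero row(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  cs <- tcrossprod(x / norms)
  cs <- pmin(pmax(cs, -1), 1)
  aff <- 1 - acos(cs) / pi
  diag(aff) <- 1
  parcel_matrix(aff, kind = "affinity", parcel_ids = rownames(x))
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Density-normalizes the affinity (`W_alpha = D^-alpha W D^-alpha`,
#' `alpha = 0.5` by default), row-normalizes to a Markov operator, and takes
#' its leading nontrivial right eigenvectors as gradients. With
#' `diffusion_time = 0` components are scaled by `lambda / (1 - lambda)`
#' (multi-scale convention); otherwise by `lambda^t`. Variance explained is
#' each nontrivial eigenvalue over the sum of retained nontrivial
#' eigenvalues. Signs are fixed so each gradient correlates non-negatively
#' with `anchor` (when given) or has its largest-magnitude loading positive.
#'
#' The eigenproblem is solved densely via the conjugate symmetric operator,
#' so the embedding is deterministic; `seed` is accepted for interface
#' parity only.
#'
#' @param affinity A `parcel_matrix` of kind `"affinity"` (or non-negative
#'   symmetric matrix); must be connected.
#' @param n_components Number of gradients `k`.
#' @param alpha Density-normalization exponent in [0, 1].
#' @param diffusion_time Diffusion time `t` (0 = multi-scale).
#' @param anchor Optional numeric vector (e.g. a centroid coordinate) that
#'   fixes gradient signs.
#' @param seed Unused; deterministic.
#' @return A `gradient_set`: `coords` (p x k), `eigenvalues`,
#'   `variance_explained`, `alpha`, `diffusion_time`, `source_kind`.
#' @export
diffusion_embedding <- function(affinity, n_components = 10, alpha = 0.5,
                                diffusion_time = 0, anchor = NULL, seed = NULL) {
  w <- pm_values(affinity)
  kind <- if (inherits(affinity, "parcel_matrix")) affinity$kind else "affinity"
  p <- nrow(w)
  n_components <- min(n_components, p - 1)
  if (min(w) < 0) stop("affinity must be non-negative", call. = FALSE)
  comp <- connected_components_dense(w)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop(
      "affinity graph is disconnected; component sizes: ",
      paste(sizes, collapse = ", "),
      call. = FALSE
    )
  }
  d <- rowSums(w)
  w_alpha <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w_alpha)
  # conjugate symmetric operator; right eigenvectors of P = D1^-1 W_alpha
  s <- w_alpha / outer(sqrt(d1), sqrt(d1))
  es <- eigen((s + t(s)) / 2, symmetric = TRUE)
  lam <- es$values
  phi <- es$vectors / sqrt(d1) # right eigenvectors of P, columns
  # normalize against the trivial (constant) eigenvector
  phi <- phi / phi[1, 1]
  psi <- phi[, 2:(n_components + 1), drop = FALSE]
  lam_k <- lam[2:(n_components + 1)]
  scale_k <- if (diffusion_time == 0) lam_k / (1 - lam_k) else lam_k^diffusion_time
  coords <- sweep(psi, 2, scale_k, `*`)
  # sign convention
  for (j in seq_len(ncol(coords))) {
    s_j <- if (!is.null(anchor)) {
      sign(stats::cor(coords[, j], anchor))
    } else {
      sign(coords[which.max(abs(coords[, j])), j])
    }
    if (!is.na(s_j) && s_j < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(w)
  colnames(coords) <- paste0("G", seq_len(ncol(coords)))
  structure(
    list(
      coords = coords,
      eigenvalues = lam_k,
      variance_explained = lam_k / sum(lam_k),
      alpha = alpha,
      diffusion_time = diffusion_time,
      source_kind = kind
    ),
    class = "gradient_set"
  )
}

connected_components_dense <- function(w) {
  p <- nrow(w)
  comp <- integer(p)
  cur <- 0L
  for (start in seq_len(p)) {
    if (comp[start] != 0) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(w[v, ] > 0 & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.gradient_set <- function(x, ...) {
  ve <- paste0(round(100 * x$variance_explained[1:min(3, length(x$variance_explained))]), "%")
  cat(
    "<gradient_set> ", nrow(x$coords), " parcels x ", ncol(x$coords),
    " gradients (", x$source_kind, "); variance explained: ",
    paste(ve, collapse = ", "), ", ...\n",
    sep = ""
  )
  invisible(x)
}

#' Gradient coordinates in long form
#' @param x A `gradient_set`.
#' @param ... Unused.
#' @return Tibble: parcel_id, gradient, score.
#' @export
tidy.gradient_set <- function(x, ...) {
  tibble::as_tibble(x$coords, rownames = "parcel_id") |>
    tidyr::pivot_longer(-"parcel_id", names_to = "gradient", values_to = "score")
}

#' @export
glance.gradient_set <- function(x, ...) {
  tibble::tibble(
    n_parcels = nrow(x$coords),
    n_components = ncol(x$coords),
    alpha = x$alpha,
    lambda_1 = x$eigenvalues[1],
    var_explained_1 = x$variance_explained[1],
    var_explained_2 = x$variance_explained[2]
  )
}

#' Bin parcels along a gradient and average a source matrix by bin
#'
#' Ranks parcels by gradient score, cuts them into `n_bins` groups whose
#' sizes differ by at most one (contiguous in rank), and averages the source
#' matrix within and between bins (diagonal excluded).
#'
#' @param grad Numeric gradient scores (one per parcel) or a `gradient_set`
#'   (first column used).
#' @param source A `parcel_matrix` or symmetric matrix to summarise.
#' @param n_bins Number of bins (default 10).
#' @return A `gradient_bins`: `assignment` (parcel bin index) and
#'   `bin_matrix` (n_bins x n_bins mean source values).
#' @export
bin_gradient <- function(grad, source, n_bins = 10) {
  if (inherits(grad, "gradient_set")) grad <- grad$coords[, 1]
  vals <- pm_values(source)
  p <- length(grad)
  stopifnot(n_bins <= p, nrow(vals) == p)
  rk <- rank(grad, ties.method = "first")
  assignment <- ceiling(rk * n_bins / p)
  bm <- matrix(NA_real_, n_bins, n_bins)
  for (a in seq_len(n_bins)) {
    for (b in a:n_bins) {
      ia <- which(assignment == a)
      ib <- which(assignment == b)
      if (a == b) {
        sub <- vals[ia, ia, drop = FALSE]
        bm[a, a] <- mean(sub[upper.tri(sub)])
      } else {
        bm[a, b] <- bm[b, a] <- mean(vals[ia, ib])
      }
    }
  }
  structure(
    list(n_bins = n_bins, assignment = assignment, bin_matrix = bm),
    class = "gradient_bins"
  )
}

#' @export
print.gradient_bins <- function(x, ...) {
  cat(
    "<gradient_bins> ", x$n_bins, " bins, sizes ",
    paste(tabulate(x$assignment, x$n_bins), collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.gradient_bins <- function(x, ...) {
  idx <- which(!lower.tri(x$bin_matrix), arr.ind = TRUE)
  tibble::tibble(
    bin_i = idx[, 1], bin_j = idx[, 2],
    mean_value = x$bin_matrix[idx]
  )
}

#' Match gradient columns across two embeddings
#'
#' Greedily pairs columns of `a` with the columns of `b` that maximize
#' absolute Pearson correlation (largest |r| first), and reports the signed
#' correlation after the optimal sign flip.
#'
#' @param a,b `gradient_set` objects (or p x k matrices) on the same parcels.
#' @return Tibble: gradient_a, gradient_b, r (after sign flip), sign_flipped.
#' @export
align_gradients <- function(a, b) {
  ca <- if (inherits(a, "gradient_set")) a$coords else as.matrix(a)
  cb <- if (inherits(b, "gradient_set")) b$coords else as.matrix(b)
  if (nrow(ca) != nrow(cb)) stop("gradient sets are on different parcel sets", call. = FALSE)
  r <- stats::cor(ca, cb)
  ka <- ncol(ca)
  kb <- ncol(cb)
  n_match <- min(ka, kb)
  res <- vector("list", n_match)
  absr <- abs(r)
  for (m in seq_len(n_match)) {
    ij <- which(absr == max(absr), arr.ind = TRUE)[1, ]
    r_ij <- r[ij[1], ij[2]]
    res[[m]] <- tibble::tibble(
      gradient_a = colnames(ca)[ij[1]] %||% paste0("a", ij[1]),
      gradient_b = colnames(cb)[ij[2]] %||% paste0("b", ij[2]),
      r = abs(r_ij),
      sign_flipped = r_ij < 0
    )
    absr[ij[1], ] <- -Inf
    absr[, ij[2]] <- -Inf
  }
  dplyr::arrange(dplyr::bind_rows(res), .data$gradient_a)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
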