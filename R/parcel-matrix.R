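#' Symmetric parcel-by-parcel matrix
#'
#' Light wrapper around a symmetric numeric matrix carrying its kind
#' (covariance, genetic_correlation, environmental_correlation,
#' phenotypic_correlation, distance, affinity, mpc) and provenance metadata.
#'
#' @param values p x p numeric matrix.
#' @param kind One of the recognised kinds.
#' @param parcel_ids Ordered parcel labels (default from dimnames or 1..p).
#' @param meta Named list of provenance fields (covariates removed, n, ...).
#' @return A `parcel_matrix`.
#' @export
parcel_matrix <- function(values,
                          kind = c(
                            "covariance", "genetic_correlation",
                            "environmental_correlation",
                            "phenotypic_correlation", "distance",
                            "affinity", "mpc"
                          ),
                          parcel_ids = NULL, meta = list()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  asym <- max(abs(values - t(values)), na.rm = TRUE)
  if (asym > 1e-10) stop("matrix not symmetric (max asymmetry ", asym, ")", call. = FALSE)
  values <- (values + t(values)) / 2
  corr_kinds <- c(
    "genetic_correlation", "environmental_correlation",
    "phenotypic_correlation", "affinity", "mpc"
  )
  if (kind %in% corr_kinds) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1 - 1e-8 || rng[2] > 1 + 1e-8) {
      stop("correlation-kind matrix has entries outside [-1, 1]", call. = FALSE)
    }
  }
  if (kind == "distance") {
    if (min(values, na.rm = TRUE) < 0) stop("distance matrix has negative entries", call. = FALSE)
  }
  if (is.null(parcel_ids)) {
    parcel_ids <- if (!is.null(rownames(values))) rownames(values) else paste0("p", seq_len(nrow(values)))
  }
  dimnames(values) <- list(parcel_ids, parcel_ids)
  structure(
    list(values = values, kind = kind, parcel_ids = parcel_ids, meta = meta),
    class = "parcel_matrix"
  )
}

#' @export
print.parcel_matrix <- function(x, ...) {
  cat(
    "<parcel_matrix:", x$kind, "> ", nrow(x$values), " x ", ncol(x$values),
    if (length(x$meta)) paste0(" [", paste(names(x$meta), collapse = ", "), "]") else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.matrix.parcel_matrix <- function(x, ...) x$values

#' Long-format view of a parcel matrix
#'
#' @param x A `parcel_matrix`.
#' @param ... Unused.
#' @return Tibble of the upper triangle: parcel_i, parcel_j, value.
#' @export
tidy.parcel_matrix <- function(x, ...) {
  p <- nrow(x$values)
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    parcel_i = x$parcel_ids[ut[, 1]],
    parcel_j = x$parcel_ids[ut[, 2]],
    value = x$values[ut]
  )
}

pm_values <- function(x) if (inherits(x, "parcel_matrix")) x$values else as.matrix(x)
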