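fmt_num <- function(x) {
  # %.17g survives a double -> text -> double round trip exactly
  gsub(" ", "", formatC(x, format = "g", digits = 17))
}

#' Write / read a parcel matrix as TSV with a JSON sidecar
#'
#' The TSV carries a parcel-id header row and first column; values are
#' written with 17 significant digits so the round trip is exact. Kind and
#' provenance metadata go to `<path>.json`.
#'
#' @param mat A `parcel_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  v <- mat$values
  chr <- matrix(fmt_num(v), nrow(v))
  chr[is.na(v)] <- "NA"
  lines <- c(
    paste(c("parcel_id", mat$parcel_ids), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(mat$parcel_ids[i], chr[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  jsonlite::write_json(
    list(kind = mat$kind, parcel_ids = mat$parcel_ids, meta = mat$meta),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_matrix
#' @param kind Fallback kind when no sidecar exists.
#' @return For `read_matrix`: the reconstructed `parcel_matrix`.
#' @export
read_matrix <- function(path, kind = "covariance") {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "parcel_id") {
    stop("malformed matrix header in ", path, ": first field is '", header[1],
      "', expected 'parcel_id'",
      call. = FALSE
    )
  }
  ids <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  p <- length(ids)
  bad <- which(lengths(body) != p + 1)
  if (length(bad) > 0) {
    stop("malformed matrix row at line ", bad[1] + 1, " of ", path, call. = FALSE)
  }
  vals <- t(vapply(body, function(x) {
    xx <- x[-1]
    xx[xx == "NA"] <- NA_character_
    as.numeric(xx)
  }, numeric(p)))
  side <- paste0(path, ".json")
  meta <- list()
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    kind <- js$kind
    meta <- as.list(js$meta)
  }
  parcel_matrix(vals, kind = kind, parcel_ids = ids, meta = meta)
}

#' Write / read a twin cohort (phenotype TSV + pedigree CSV)
#'
#' Phenotypes: one row per subject, `subject_id` then one column per parcel.
#' Pedigree: subject_id, family_id, zygosity, age, sex, site. Values are
#' written with full precision.
#'
#' @param cohort A `twin_cohort`.
#' @param pheno_path,pedigree_path Output paths.
#' @return Paths, invisibly.
#' @export
write_cohort <- function(cohort, pheno_path, pedigree_path) {
  th <- cohort$thickness
  lines <- c(
    paste(c("subject_id", colnames(th)), collapse = "\t"),
    vapply(seq_len(nrow(th)), function(i) {
      paste(c(cohort$pheno$subject_id[i], fmt_num(th[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, pheno_path)
  ped <- cohort$pheno
  ped$age <- fmt_num(ped$age)
  utils::write.csv(ped, pedigree_path, row.names = FALSE, quote = FALSE)
  invisible(c(pheno_path, pedigree_path))
}

#' @rdname write_cohort
#' @return For `read_cohort`: the reconstructed `twin_cohort`.
#' @export
read_cohort <- function(pheno_path, pedigree_path) {
  lines <- readLines(pheno_path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "subject_id") {
    stop("malformed phenotype header in ", pheno_path, call. = FALSE)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  th <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(length(header) - 1)))
  colnames(th) <- header[-1]
  rownames(th) <- vapply(body, `[[`, character(1), 1)
  ped <- tibble::as_tibble(utils::read.csv(pedigree_path, stringsAsFactors = FALSE))
  if (!identical(ped$subject_id, rownames(th))) {
    stop("pedigree subject ids do not match phenotype rows", call. = FALSE)
  }
  for (z in c("MZ", "DZ")) {
    sizes <- table(ped$family_id[ped$zygosity == z])
    if (any(sizes != 2)) {
      stop(z, " family without exactly 2 members: ",
        names(sizes)[sizes != 2][1],
        call. = FALSE
      )
    }
  }
  structure(list(pheno = ped, thickness = th), class = "twin_cohort")
}

#' Write / read a triangle mesh as ASCII PLY
#'
#' @param mesh A `cortex_mesh` (vertices + faces).
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(v)),
    "property double x", "property double y", "property double z",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vl <- paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3]))
  fl <- paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1)
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @return For `read_mesh_ply`: a `cortex_mesh`.
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  end <- which(lines == "end_header")[1]
  if (is.na(end)) stop("malformed PLY: missing end_header in ", path, call. = FALSE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines[1:end], value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines[1:end], value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1) {
    stop("malformed PLY header in ", path, call. = FALSE)
  }
  vlines <- strsplit(lines[(end + 1):(end + nv)], " ", fixed = TRUE)
  v <- t(vapply(vlines, function(x) as.numeric(x[1:3]), numeric(3)))
  flines <- strsplit(lines[(end + nv + 1):(end + nv + nf)], " ", fixed = TRUE)
  f <- t(vapply(flines, function(x) as.integer(x[2:4]), integer(3))) + 1L
  structure(list(vertices = v, faces = f), class = "cortex_mesh")
}

#' Write parcellation geometry (mesh PLY + parcel-map CSV + metadata JSON)
#'
#' @param geom A `parcel_geometry`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_geometry <- function(geom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh_ply(geom$mesh, file.path(dir, "mesh.ply"))
  utils::write.csv(
    data.frame(
      vertex = seq_along(geom$vertex_to_parcel),
      parcel_id = ifelse(is.na(geom$vertex_to_parcel), "medial-wall",
        as.character(geom$vertex_to_parcel)
      )
    ),
    file.path(dir, "vertex_to_parcel.csv"),
    row.names = FALSE, quote = FALSE
  )
  utils::write.csv(
    tidy.parcel_geometry(geom),
    file.path(dir, "parcels.csv"),
    row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(radius = geom$radius, seed_points = geom$seed_points),
    file.path(dir, "geometry.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
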