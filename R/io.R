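#' Read an expression dataset from delimited text files
#'
#' The matrix file holds samples as rows (first column `sample_id`, remaining
#' columns one gene each); the metadata file is keyed by `sample_id` and may
#' carry `x`, `y`, `z` (mm), `region`, `donor`, `age_pcw`, `species` columns.
#' The delimiter (tab or comma) is auto-detected per file and logged. Genes
#' with more than `max_missing` missing values are dropped; remaining missing
#' cells are imputed with the gene's mean over observed samples. Drop and
#' imputation counts are reported via `message()`.
#'
#' @param matrix_path path to the expression table.
#' @param metadata_path path to the per-sample metadata table.
#' @param max_missing maximal tolerated fraction of missing values per gene
#'   (default 0.1).
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path, max_missing = 0.1) {
  sep_m <- detect_delim(matrix_path)
  sep_d <- detect_delim(metadata_path)
  message("read_expression: delimiter '",
          if (sep_m == "\t") "tab" else "comma", "' for matrix, '",
          if (sep_d == "\t") "tab" else "comma", "' for metadata")
  mat <- utils::read.table(matrix_path, header = TRUE, sep = sep_m,
                           check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.table(metadata_path, header = TRUE, sep = sep_d,
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(mat)) stop("matrix file lacks sample_id column")
  if (!"sample_id" %in% names(meta)) stop("metadata file lacks sample_id column")
  sids <- as.character(mat$sample_id)
  if (anyDuplicated(sids)) {
    stop("duplicate sample ids in matrix: ",
         paste(utils::head(unique(sids[duplicated(sids)]), 5), collapse = ", "))
  }
  x <- as.matrix(mat[, setdiff(names(mat), "sample_id"), drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- sids
  if (anyDuplicated(colnames(x))) {
    stop("duplicate gene ids: ",
         paste(utils::head(unique(colnames(x)[duplicated(colnames(x))]), 5),
               collapse = ", "))
  }
  missing_meta <- setdiff(sids, meta$sample_id)
  if (length(missing_meta)) {
    stop("metadata missing for sample(s): ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  }
  meta <- meta[match(sids, meta$sample_id), , drop = FALSE]

  # Missing-data policy: drop genes with > max_missing missing, mean-impute rest.
  na_frac <- colMeans(is.na(x))
  drop <- na_frac > max_missing
  if (any(drop)) {
    message("read_expression: dropped ", sum(drop), " gene(s) with >",
            round(100 * max_missing), "% missing values")
    x <- x[, !drop, drop = FALSE]
  }
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
    message("read_expression: mean-imputed ", n_imputed, " missing cell(s)")
  }
  coords <- NULL
  if (all(c("x", "y", "z") %in% names(meta))) {
    coords <- as.matrix(meta[, c("x", "y", "z")])
  }
  expression_dataset(
    x, coords = coords,
    region = if ("region" %in% names(meta)) meta$region,
    donor = if ("donor" %in% names(meta)) meta$donor,
    age_pcw = if ("age_pcw" %in% names(meta)) meta$age_pcw,
    species = if ("species" %in% names(meta)) meta$species[1] else "unknown")
}

#' Write an expression dataset to delimited text files
#'
#' Inverse of [read_expression()]; round-trips valid datasets.
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,metadata_path output paths.
#' @param sep field delimiter (default tab).
#' @export
write_expression <- function(ds, matrix_path, metadata_path, sep = "\t") {
  stopifnot(inherits(ds, "expression_dataset"))
  mat <- data.frame(sample_id = ds$sample_ids, check.names = FALSE)
  mat <- cbind(mat, as.data.frame(ds$expression, check.names = FALSE))
  utils::write.table(mat, matrix_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  meta <- data.frame(sample_id = ds$sample_ids, region = ds$region,
                     donor = ds$donor, species = ds$species,
                     check.names = FALSE)
  if (!is.null(ds$coords)) {
    meta$x <- ds$coords[, 1]; meta$y <- ds$coords[, 2]; meta$z <- ds$coords[, 3]
  }
  if (!is.null(ds$age_pcw)) meta$age_pcw <- ds$age_pcw
  utils::write.table(meta, metadata_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(ds)
}

# ---- surfaces ----------------------------------------------------------------

#' Construct a surface pair
#'
#' An anatomical cortical mesh plus its matched registration sphere (unit
#' radius, same vertex order and faces) and a per-vertex medial-wall mask
#' (TRUE = excluded from analysis).
#'
#' @param anat_vertices numeric `n_vertices x 3` matrix, mm.
#' @param sphere_vertices numeric `n_vertices x 3` matrix; rows must have unit
#'   norm within `1e-3` and are renormalized to machine precision.
#' @param faces integer `n_faces x 3` matrix of 1-based vertex indices.
#' @param medial_mask logical per vertex; default all `FALSE`.
#' @return object of class `surface_pair`.
#' @export
surface_pair <- function(anat_vertices, sphere_vertices, faces,
                         medial_mask = NULL) {
  anat_vertices <- as.matrix(anat_vertices)
  sphere_vertices <- as.matrix(sphere_vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  nv <- nrow(anat_vertices)
  if (nrow(sphere_vertices) != nv) {
    stop("vertex-count mismatch: anatomical ", nv, " vs sphere ",
         nrow(sphere_vertices))
  }
  if (ncol(anat_vertices) != 3L || ncol(sphere_vertices) != 3L ||
      ncol(faces) != 3L) stop("vertices and faces must have 3 columns")
  nrm <- sqrt(rowSums(sphere_vertices^2))
  if (any(abs(nrm - 1) > 1e-3)) {
    stop("sphere vertex norms deviate from 1 by more than 1e-3 (max dev ",
         signif(max(abs(nrm - 1)), 3), ")")
  }
  sphere_vertices <- sphere_vertices / nrm
  if (min(faces) < 1L || max(faces) > nv) stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
          faces[, 2] == faces[, 3])) stop("degenerate faces present")
  if (is.null(medial_mask)) medial_mask <- rep(FALSE, nv)
  medial_mask <- as.logical(medial_mask)
  if (length(medial_mask) != nv) stop("medial mask length mismatch")
  structure(list(anat_vertices = anat_vertices,
                 sphere_vertices = sphere_vertices,
                 faces = faces, medial_mask = medial_mask),
            class = "surface_pair")
}

#' @export
print.surface_pair <- function(x, ...) {
  cat("surface_pair:", nrow(x$anat_vertices), "vertices,",
      nrow(x$faces), "faces,", sum(x$medial_mask), "masked\n")
  invisible(x)
}

# Write one mesh in plain-text OFF format.
write_off <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(vertices), nrow(faces), 0L), con)
  utils::write.table(format(vertices, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  faces <- NULL
  if (nf > 0) {
    fr <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 nrow = nf, byrow = TRUE)
    faces <- fr[, 2:4, drop = FALSE] + 1L
    storage.mode(faces) <- "integer"
  }
  list(vertices = verts, faces = faces)
}

#' Read a surface pair from plain-text OFF meshes
#'
#' @param anat_path path to the anatomical mesh (OFF).
#' @param sphere_path path to the matched sphere mesh (OFF, unit radius within
#'   1e-3; renormalized on load).
#' @param mask_path optional path to a text file with one 0/1 per vertex
#'   (1 = medial wall, excluded).
#' @return a [surface_pair()].
#' @export
read_surface <- function(anat_path, sphere_path, mask_path = NULL) {
  anat <- read_off(anat_path)
  sph <- read_off(sphere_path)
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.logical(scan(mask_path, quiet = TRUE))
  }
  surface_pair(anat$vertices, sph$vertices, anat$faces, medial_mask = mask)
}

#' Write a surface pair to plain-text OFF meshes
#'
#' @param surf a [surface_pair()].
#' @param anat_path,sphere_path,mask_path output paths (mask optional).
#' @export
write_surface <- function(surf, anat_path, sphere_path, mask_path = NULL) {
  stopifnot(inherits(surf, "surface_pair"))
  write_off(surf$anat_vertices, surf$faces, anat_path)
  write_off(surf$sphere_vertices, surf$faces, sphere_path)
  if (!is.null(mask_path)) {
    writeLines(as.character(as.integer(surf$medial_mask)), mask_path)
  }
  invisible(surf)
}

# ---- model serialization -----------------------------------------------------

MODEL_FORMAT <- "spatiomol-pls"
MODEL_VERSION <- 1L

#' Save a fitted PLS gradient model to JSON
#'
#' The format is versioned; numbers are written at full double precision so
#' that `load_model(save_model(m))` reproduces predictions to better than
#' 1e-12 relative error.
#'
#' @param model a fitted [fit_pls()] model.
#' @param path output path (JSON).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
              k = model$k, gene_ids = model$gene_ids,
              gene_mean = model$gene_mean, gene_sd = model$gene_sd,
              coord_mean = model$coord_mean,
              W = model$W, P = model$P, C = model$C, B = model$B,
              T = model$T, U = model$U,
              sign_anchor = model$sign_anchor,
              train_ids = model$train_ids)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted PLS gradient model from JSON
#'
#' @param path path written by [save_model()].
#' @return a `pls_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(obj$format) || obj$format != MODEL_FORMAT) {
    stop("not a ", MODEL_FORMAT, " file: ", path)
  }
  if (is.null(obj$version) || obj$version != MODEL_VERSION) {
    stop("model format version mismatch: file has '", obj$version,
         "', this package reads '", MODEL_VERSION, "'")
  }
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  m <- list(k = as.integer(obj$k), gene_ids = as.character(obj$gene_ids),
            gene_mean = as.numeric(obj$gene_mean),
            gene_sd = as.numeric(obj$gene_sd),
            coord_mean = as.numeric(obj$coord_mean),
            W = as_mat(obj$W), P = as_mat(obj$P), C = as_mat(obj$C),
            B = as_mat(obj$B), T = as_mat(obj$T), U = as_mat(obj$U),
            sign_anchor = as.integer(obj$sign_anchor),
            train_ids = as.character(obj$train_ids))
  names(m$gene_mean) <- names(m$gene_sd) <- m$gene_ids
  rownames(m$W) <- rownames(m$P) <- rownames(m$B) <- m$gene_ids
  class(m) <- "pls_model"
  m
}
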