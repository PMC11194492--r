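#' Expression dataset container
#'
#' Bundles a sample-by-gene expression matrix with per-sample metadata:
#' optional 3D stereotaxic coordinates (mm), region labels, donor ids,
#' optional donor age in post-conception weeks, and a species tag. This is the
#' single input container consumed by every analysis stage.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#'   Row names are sample ids and column names gene ids (supplied names win
#'   over `sample_ids`/`gene_ids` arguments when both are given).
#' @param coords numeric matrix `n_samples x 3` of mm coordinates in a
#'   right-handed space (x: left-right, y: posterior-anterior,
#'   z: inferior-superior), or `NULL` for region-only datasets.
#' @param region character vector of region labels per sample.
#' @param donor character vector of donor ids per sample (default one donor).
#' @param age_pcw single positive number or per-sample vector, age in
#'   post-conception weeks, or `NULL` when unknown.
#' @param species species tag string.
#' @param sample_ids,gene_ids identifiers used when `expression` has no
#'   dimnames.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `expression`, `coords`, `region`, `donor`, `age_pcw`, `species`,
#'   `sample_ids`, `gene_ids`.
#' @export
expression_dataset <- function(expression, coords = NULL, region = NULL,
                               donor = NULL, age_pcw = NULL,
                               species = "synthetic",
                               sample_ids = NULL, gene_ids = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  n <- nrow(expression)
  g <- ncol(expression)
  if (!is.null(rownames(expression))) sample_ids <- rownames(expression)
  if (!is.null(colnames(expression))) gene_ids <- colnames(expression)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(g))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != n) stop("sample_ids length does not match rows")
  if (length(gene_ids) != g) stop("gene_ids length does not match columns")
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(utils::head(unique(
      gene_ids[duplicated(gene_ids)]), 5), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(utils::head(unique(
      sample_ids[duplicated(sample_ids)]), 5), collapse = ", "))
  }
  if (anyNA(expression) || any(!is.finite(expression))) {
    stop("expression contains non-finite values; clean or impute first ",
         "(see read_expression)")
  }
  dimnames(expression) <- list(sample_ids, gene_ids)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != n || ncol(coords) != 3L) {
      stop("coords must be n_samples x 3; got ", nrow(coords), " x ",
           ncol(coords), " for ", n, " samples")
    }
    if (any(!is.finite(coords))) {
      bad <- which(!stats::complete.cases(coords) |
                     apply(!is.finite(coords), 1, any))
      stop("non-finite coordinates for sample(s): ",
           paste(utils::head(sample_ids[bad], 5), collapse = ", "))
    }
    dimnames(coords) <- list(sample_ids, c("x", "y", "z"))
  }
  if (is.null(region)) region <- rep("all", n)
  region <- as.character(region)
  if (length(region) != n) stop("region labels length mismatch")
  if (is.null(donor)) donor <- rep("d1", n)
  donor <- as.character(rep_len(donor, n))
  if (!is.null(age_pcw)) {
    age_pcw <- as.numeric(rep_len(age_pcw, n))
    if (any(!is.finite(age_pcw)) || any(age_pcw <= 0)) {
      stop("age_pcw must be positive and finite where present")
    }
  }
  structure(list(expression = expression, coords = coords, region = region,
                 donor = donor, age_pcw = age_pcw, species = species,
                 sample_ids = sample_ids, gene_ids = gene_ids),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$expression), "samples x",
      ncol(x$expression), "genes\n")
  cat("  coords:", if (is.null(x$coords)) "absent" else "present (mm)",
      "| regions:", length(unique(x$region)),
      "| donors:", length(unique(x$donor)),
      "| species:", x$species, "\n")
  if (!is.null(x$age_pcw)) {
    cat("  age_pcw range:", paste(signif(range(x$age_pcw), 4),
                                  collapse = " - "), "\n")
  }
  invisible(x)
}

#' Subset an expression dataset
#'
#' @param ds an [expression_dataset()].
#' @param samples integer/logical/character index of samples to keep
#'   (default all).
#' @param genes index of genes to keep (default all).
#' @return the subset `expression_dataset`.
#' @export
ds_subset <- function(ds, samples = NULL, genes = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  si <- samples %||% seq_along(ds$sample_ids)
  gi <- genes %||% seq_along(ds$gene_ids)
  if (is.character(si)) si <- match(si, ds$sample_ids)
  if (is.character(gi)) gi <- match(gi, ds$gene_ids)
  expression_dataset(
    ds$expression[si, gi, drop = FALSE],
    coords = if (!is.null(ds$coords)) ds$coords[si, , drop = FALSE],
    region = ds$region[si], donor = ds$donor[si],
    age_pcw = if (!is.null(ds$age_pcw)) ds$age_pcw[si],
    species = ds$species)
}

#' Gradient scores container
#'
#' Latent-variable scores per sample, region, or vertex.
#'
#' @param ids character ids of the scored units.
#' @param scores numeric matrix `n x k`.
#' @param level one of `"sample"`, `"region"`, `"vertex"`.
#' @return object of class `gradient_scores`.
#' @export
gradient_scores <- function(ids, scores, level = c("sample", "region", "vertex")) {
  level <- match.arg(level)
  scores <- as.matrix(scores)
  stopifnot(length(ids) == nrow(scores), all(is.finite(scores)))
  rownames(scores) <- ids
  colnames(scores) <- paste0("LV", seq_len(ncol(scores)))
  structure(list(ids = as.character(ids), scores = scores, level = level),
            class = "gradient_scores")
}

#' @export
print.gradient_scores <- function(x, ...) {
  cat("gradient_scores:", nrow(x$scores), x$level, "units x",
      ncol(x$scores), "components\n")
  invisible(x)
}
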