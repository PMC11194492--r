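#' Select top gradient-associated genes by weight tails
#'
#' Splits a family-wise selection budget `alpha` evenly across tails and
#' components: the per-tail fraction is `alpha / (n_tails * n_components)`
#' and the per-tail count `floor(n_genes * fraction)` (with 15,634 genes,
#' `alpha = 0.05`, two tails and three components this yields 130 genes per
#' tail). Ranking is by signed weight; ties are broken deterministically by
#' gene id.
#'
#' @param weight_matrix numeric `n_genes x k` matrix of gene weights with
#'   gene ids as rownames (e.g. a model's `W`).
#' @param alpha total selection fraction in (0, 1), default 0.05.
#' @param n_tails 1 or 2.
#' @param n_components number of components sharing the budget (defaults to
#'   `ncol(weight_matrix)`).
#' @return object of class `gene_selection`: `per_tail_count`, `alpha`,
#'   `n_tails`, `n_components`, `tails` (list per component with `positive`
#'   and `negative` data.frames of gene_id/weight), `membership` (logical
#'   gene x component matrix of union-of-tails membership), `multiplicity`
#'   (named integer per selected gene).
#' @export
select_top_genes <- function(weight_matrix, alpha = 0.05, n_tails = 2,
                             n_components = ncol(weight_matrix)) {
  weight_matrix <- as.matrix(weight_matrix)
  if (is.null(rownames(weight_matrix))) {
    rownames(weight_matrix) <- sprintf("g%05d", seq_len(nrow(weight_matrix)))
  }
  stopifnot(alpha > 0, alpha < 1, n_tails %in% c(1L, 2L))
  n_genes <- nrow(weight_matrix)
  frac <- alpha / (n_tails * n_components)
  # epsilon guards against floating-point round-down of exact ratios
  n_per_tail <- floor(n_genes * frac + 1e-9)
  if (n_per_tail == 0) {
    stop("per-tail count is 0 at alpha = ", alpha,
         "; increase alpha or supply more genes")
  }
  ids <- rownames(weight_matrix)
  k <- ncol(weight_matrix)
  tails <- vector("list", k)
  membership <- matrix(FALSE, n_genes, k,
                       dimnames = list(ids, paste0("LV", seq_len(k))))
  for (j in seq_len(k)) {
    w <- weight_matrix[, j]
    pos_ord <- order(-w, ids)[seq_len(n_per_tail)]
    neg_ord <- order(w, ids)[seq_len(n_per_tail)]
    tails[[j]] <- list(
      positive = data.frame(gene_id = ids[pos_ord], weight = w[pos_ord],
                            row.names = NULL),
      negative = data.frame(gene_id = ids[neg_ord], weight = w[neg_ord],
                            row.names = NULL))
    membership[pos_ord, j] <- TRUE
    if (n_tails == 2L) membership[neg_ord, j] <- TRUE
  }
  mult <- rowSums(membership)
  mult <- mult[mult > 0]
  structure(list(per_tail_count = n_per_tail, alpha = alpha,
                 n_tails = as.integer(n_tails),
                 n_components = as.integer(n_components),
                 tails = tails, membership = membership,
                 multiplicity = mult),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("gene_selection:", x$per_tail_count, "genes per tail (alpha",
      x$alpha, ",", x$n_tails, "tails x", x$n_components, "components)\n")
  cat("  selected genes:", length(x$multiplicity), "\n")
  invisible(x)
}

#' Multi-component membership (Venn) counts of selected genes
#'
#' Counts genes selected (union of both tails per component) in exactly
#' 1, 2, ..., k components.
#'
#' @param selection a [select_top_genes()] result from >= 2 components.
#' @return list with `counts` (named integer: genes in exactly m
#'   components) and `membership` table (`data.frame` gene_id, one logical
#'   column per component, multiplicity).
#' @export
component_overlap <- function(selection) {
  stopifnot(inherits(selection, "gene_selection"))
  k <- ncol(selection$membership)
  if (k < 2) stop("selection must cover >= 2 components")
  mult <- rowSums(selection$membership)
  sel <- mult > 0
  counts <- vapply(seq_len(k), function(m) sum(mult[sel] == m), integer(1))
  names(counts) <- paste0("in_", seq_len(k))
  tab <- data.frame(gene_id = rownames(selection$membership)[sel],
                    selection$membership[sel, , drop = FALSE],
                    multiplicity = mult[sel], row.names = NULL)
  list(counts = counts, membership = tab)
}

#' Permutation overlap test between a target list and a reference gene set
#'
#' Observed statistic: the fraction of target genes contained in the
#' reference set. The null draws `n_perm` seeded random reference-sized sets
#' from the universe; `p = (1 + #{null >= observed}) / (n_perm + 1)` (always
#' in (0, 1]). The null mean converges to the hypergeometric expectation
#' `|reference| / |universe|`.
#'
#' @param target_list character vector of target genes (subset of universe;
#'   non-empty).
#' @param reference_list character vector (subset of universe).
#' @param universe character vector of all eligible genes.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return object of class `overlap_test`: `observed_fraction`, `null_mean`,
#'   `null_ci` (2.5-97.5 percentiles), `p_perm`, `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(target_list, reference_list, universe,
                                     n_perm = 999, seed = 1) {
  target_list <- unique(as.character(target_list))
  reference_list <- unique(as.character(reference_list))
  universe <- unique(as.character(universe))
  if (length(target_list) == 0) stop("target list is empty")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (length(setdiff(target_list, universe))) {
    stop("target genes outside the universe")
  }
  if (length(setdiff(reference_list, universe))) {
    stop("reference genes outside the universe")
  }
  observed <- length(intersect(target_list, reference_list)) /
    length(target_list)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ref_b <- sample(universe, length(reference_list))
      length(intersect(target_list, ref_b)) / length(target_list)
    }, numeric(1))
  })
  structure(list(observed_fraction = observed, null_mean = mean(nulls),
                 null_ci = stats::quantile(nulls, c(0.025, 0.975)),
                 p_perm = perm_pvalue(sum(nulls >= observed), n_perm),
                 n_perm = n_perm, seed = seed, null_fractions = nulls),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("overlap_test: observed %.1f%%, null mean %.1f%% ",
                     "[95%% CI %.1f%%, %.1f%%], p_perm = %.4g (%d perms)\n"),
              100 * x$observed_fraction, 100 * x$null_mean,
              100 * x$null_ci[1], 100 * x$null_ci[2], x$p_perm, x$n_perm))
  invisible(x)
}
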