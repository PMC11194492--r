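#' Refit the PLS model on genes shared with an external dataset
#'
#' Restricts the discovery dataset to the gene intersection (after applying
#' an optional external-to-discovery gene-id mapping, e.g. for cross-species
#' homologs), refits, and aligns the refit components to the full-gene model
#' by maximal |score correlation| (optimal pairing), with signs aligned to
#' positive correlation.
#'
#' @param discovery discovery [expression_dataset()] with coordinates.
#' @param external_gene_ids character gene ids present in the external data.
#' @param k number of components.
#' @param min_shared minimum shared gene count (default 50).
#' @param mapping optional two-column data.frame (external id, discovery id)
#'   applied to `external_gene_ids` before intersecting.
#' @param full_model optional pre-fitted full-gene model to align against
#'   (refitted internally when `NULL`).
#' @return the aligned shared-gene `pls_model`.
#' @export
refit_on_shared_genes <- function(discovery, external_gene_ids, k = 3,
                                  min_shared = 50, mapping = NULL,
                                  full_model = NULL) {
  ids <- as.character(external_gene_ids)
  if (!is.null(mapping)) {
    mapping <- as.data.frame(mapping)
    hit <- match(ids, as.character(mapping[[1]]))
    ids <- as.character(mapping[[2]])[hit[!is.na(hit)]]
  }
  shared <- intersect(discovery$gene_ids, ids)
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " shared gene(s); need at least ", min_shared)
  }
  if (is.null(full_model)) full_model <- fit_pls(discovery, k = k)
  sub_fit <- fit_pls(ds_subset(discovery, genes = shared), k = k)
  r <- stats::cor(full_model$T, sub_fit$T)
  pr <- pair_components(r)
  ord <- pr$order; sg <- pr$signs
  sub_fit$W <- sweep(sub_fit$W[, ord, drop = FALSE], 2, sg, "*")
  sub_fit$P <- sweep(sub_fit$P[, ord, drop = FALSE], 2, sg, "*")
  sub_fit$C <- sweep(sub_fit$C[, ord, drop = FALSE], 2, sg, "*")
  sub_fit$T <- sweep(sub_fit$T[, ord, drop = FALSE], 2, sg, "*")
  sub_fit$U <- sweep(sub_fit$U[, ord, drop = FALSE], 2, sg, "*")
  sub_fit$sign_anchor <- sub_fit$sign_anchor[ord]
  sub_fit$B <- sub_fit$W %*% solve(crossprod(sub_fit$P, sub_fit$W),
                                   t(sub_fit$C))
  colnames(sub_fit$W) <- colnames(sub_fit$P) <- colnames(sub_fit$C) <-
    colnames(sub_fit$T) <- colnames(sub_fit$U) <- paste0("LV", seq_len(k))
  sub_fit$alignment <- list(order = ord, signs = sg, abs_r = pr$abs_r)
  sub_fit
}

#' Region-averaged gradient scores
#'
#' Sample-level scores from [transform_scores()] averaged within region.
#'
#' @param model a fitted `pls_model`.
#' @param dataset an [expression_dataset()] with region labels.
#' @param min_samples regions with fewer samples are dropped with a warning.
#' @return a [gradient_scores()] at region level (rows named by region).
#' @export
regional_scores <- function(model, dataset, min_samples = 1) {
  if (all(dataset$region == dataset$region[1]) &&
      length(unique(dataset$region)) < 2 && dataset$region[1] == "all") {
    stop("dataset has no region labels")
  }
  s <- transform_scores(model, dataset)
  counts <- table(dataset$region)
  keep <- names(counts)[counts >= min_samples]
  if (length(keep) < length(counts)) {
    warning("dropping ", length(counts) - length(keep),
            " region(s) with fewer than ", min_samples, " samples")
  }
  sel <- dataset$region %in% keep
  m <- rowsum(s$scores[sel, , drop = FALSE], dataset$region[sel])
  m <- m / as.vector(table(dataset$region[sel])[rownames(m)])
  gradient_scores(rownames(m), m, level = "region")
}

# Null correlations of `ext` (permuted) against `disc` for each LV column.
# Exact enumeration when n! is small, Monte-Carlo otherwise.
regional_null_r <- function(disc, ext, n_perm, seed, exact_max = 8) {
  n <- nrow(disc)
  if (n <= exact_max) {
    perms <- all_perms(n)
    list(exact = TRUE,
         null = vapply(seq_len(ncol(disc)), function(j) {
           apply(perms, 1, function(p) stats::cor(disc[, j], ext[p, j]))
         }, numeric(nrow(perms))))
  } else {
    null <- with_seed(seed, {
      vapply(seq_len(ncol(disc)), function(j) {
        replicate(n_perm, stats::cor(disc[, j], ext[sample.int(n), j]))
      }, numeric(n_perm))
    })
    list(exact = FALSE, null = null)
  }
}

#' Regional similarity between discovery and external gradient expression
#'
#' Pearson correlation per component between region-averaged scores over the
#' shared regions, with a one-sided (high r) permutation p-value from
#' permuting the external regional values across regions. Regions with at
#' most 8 shared labels use exact enumeration of all permutations; larger
#' panels use seeded Monte-Carlo with the add-one formula.
#'
#' @param discovery_regional,external_regional region-level
#'   [gradient_scores()].
#' @param n_perm Monte-Carlo permutations (used when shared regions > 8).
#' @param seed RNG seed.
#' @param dataset_id,individual_id,species,age_pcw metadata carried into the
#'   record.
#' @return a one-row `data.frame` (class `similarity_record`) with columns
#'   `dataset_id`, `individual_id`, `species`, `age_pcw`, `n_regions`,
#'   `r_LV*` and `p_LV*` per component.
#' @export
regional_similarity <- function(discovery_regional, external_regional,
                                n_perm = 999, seed = 1,
                                dataset_id = "external",
                                individual_id = "indiv01",
                                species = NA_character_,
                                age_pcw = NA_real_) {
  stopifnot(inherits(discovery_regional, "gradient_scores"),
            inherits(external_regional, "gradient_scores"))
  common <- intersect(discovery_regional$ids, external_regional$ids)
  if (length(common) < 3) {
    stop("only ", length(common), " shared region(s); need at least 3")
  }
  disc <- discovery_regional$scores[common, , drop = FALSE]
  ext <- external_regional$scores[common, , drop = FALSE]
  k <- ncol(disc)
  stopifnot(ncol(ext) == k)
  r <- vapply(seq_len(k), function(j) stats::cor(disc[, j], ext[, j]),
              numeric(1))
  nr <- regional_null_r(disc, ext, n_perm, seed)
  p <- vapply(seq_len(k), function(j) {
    if (nr$exact) {
      mean(nr$null[, j] >= r[j])          # identity included: p > 0
    } else {
      perm_pvalue(sum(nr$null[, j] >= r[j]), n_perm)
    }
  }, numeric(1))
  out <- data.frame(dataset_id = dataset_id, individual_id = individual_id,
                    species = species, age_pcw = age_pcw,
                    n_regions = length(common))
  for (j in seq_len(k)) out[[paste0("r_LV", j)]] <- r[j]
  for (j in seq_len(k)) out[[paste0("p_LV", j)]] <- p[j]
  class(out) <- c("similarity_record", class(out))
  out
}

#' Average similarity records across individuals
#'
#' @param records a `data.frame` of stacked [regional_similarity()] rows.
#' @param method `"mean"` (default) or `"fisher"` (Fisher-z average).
#' @return named numeric vector of averaged r per component.
#' @export
average_similarity <- function(records, method = c("mean", "fisher")) {
  method <- match.arg(method)
  rcols <- grep("^r_LV", names(records), value = TRUE)
  vapply(rcols, function(cn) {
    r <- records[[cn]]
    if (method == "mean") mean(r) else tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12),
                                                            1 - 1e-12))))
  }, numeric(1))
}

#' Similarity-to-adult trajectories across development
#'
#' One [regional_similarity()] record per individual dataset, against the
#' adult discovery regional scores. Individuals without an age are skipped
#' with a warning. Ages are reported both raw and as natural-log pcw.
#'
#' @param model the (shared-gene) discovery `pls_model`.
#' @param developmental_datasets list of [expression_dataset()]s with region
#'   labels and `age_pcw`.
#' @param adult_reference region-level [gradient_scores()] of the adult
#'   discovery data.
#' @param n_perm,seed permutation settings passed to [regional_similarity()].
#' @return `data.frame` with one row per individual: `individual_id`,
#'   `age_pcw`, `log_age_pcw`, `r_LV*`, `p_LV*`, `n_regions`.
#' @export
developmental_trajectory <- function(model, developmental_datasets,
                                     adult_reference, n_perm = 999, seed = 1) {
  rows <- list()
  for (i in seq_along(developmental_datasets)) {
    ds <- developmental_datasets[[i]]
    if (is.null(ds$age_pcw)) {
      warning("individual ", i, " has no age; skipped")
      next
    }
    reg <- regional_scores(model, ds)
    rec <- regional_similarity(adult_reference, reg, n_perm = n_perm,
                               seed = seed + i,
                               dataset_id = "developmental",
                               individual_id = ds$donor[1],
                               species = ds$species,
                               age_pcw = ds$age_pcw[1])
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows)) stop("no individual with age information")
  out <- do.call(rbind, rows)
  out$log_age_pcw <- log(out$age_pcw)
  out
}

#' Genes most associated with an adult gradient in one epoch
#'
#' Per-gene Pearson correlation between the gene's region-averaged
#' expression and the adult regional component scores; the top
#' `floor(n_genes * top_frac)` genes by r are returned with their r values.
#' Genes with degenerate regional variance are never selected.
#'
#' @param dataset_epoch [expression_dataset()] for one developmental epoch
#'   (regions labeled; >= 3 regions).
#' @param adult_regional_lv named numeric vector: adult component score per
#'   region.
#' @param top_frac selection fraction in (0, 1), e.g. 0.01 for the top 1%.
#' @return `data.frame` `gene_id`, `r`, ordered by decreasing r (ties broken
#'   by gene id).
#' @export
find_gradient_associated_genes <- function(dataset_epoch, adult_regional_lv,
                                           top_frac = 0.01) {
  stopifnot(top_frac > 0, top_frac < 1)
  regions <- intersect(names(adult_regional_lv), unique(dataset_epoch$region))
  if (length(regions) < 3) stop("need at least 3 shared regions")
  sel <- dataset_epoch$region %in% regions
  rm_ <- rowsum(dataset_epoch$expression[sel, , drop = FALSE],
                dataset_epoch$region[sel])
  rm_ <- rm_ / as.vector(table(dataset_epoch$region[sel])[rownames(rm_)])
  rm_ <- rm_[regions, , drop = FALSE]
  lv <- adult_regional_lv[regions]
  sds <- apply(rm_, 2, stats::sd)
  r <- rep(-Inf, ncol(rm_))
  ok <- sds > 0
  r[ok] <- suppressWarnings(as.vector(stats::cor(rm_[, ok, drop = FALSE], lv)))
  n_top <- floor(length(r) * top_frac)
  if (n_top < 1) stop("top_frac too small: selects no genes")
  ord <- order(-r, colnames(rm_))
  take <- ord[seq_len(n_top)]
  data.frame(gene_id = colnames(rm_)[take], r = r[take])
}

#' Identify nontransitional genes from similarity trajectories
#'
#' k-means clustering (`nstart = 50`, seeded) of per-gene trajectories of
#' regional correlation with the adult component across ages; the selected
#' cluster maximizes the minimum (over ages) of its centroid, i.e. genes
#' that track the adult gradient at every age.
#'
#' @param trajectory_matrix numeric `genes x ages` matrix of r-to-adult.
#' @param n_clusters number of clusters (>= 2).
#' @param seed RNG seed.
#' @return list with `genes` (rownames of the selected cluster), `centroid`,
#'   `cluster` assignment vector, and `degenerate` flag (TRUE when all
#'   trajectories are identical; all genes returned, no clustering).
#' @export
nontransitional_genes <- function(trajectory_matrix, n_clusters = 3, seed = 1) {
  trajectory_matrix <- as.matrix(trajectory_matrix)
  if (ncol(trajectory_matrix) < 2) stop("need >= 2 ages")
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  uniq <- unique(trajectory_matrix)
  if (nrow(uniq) == 1L) {
    return(list(genes = rownames(trajectory_matrix),
                centroid = uniq[1, ],
                cluster = rep(1L, nrow(trajectory_matrix)),
                degenerate = TRUE))
  }
  km <- with_seed(seed, stats::kmeans(trajectory_matrix,
                                      centers = min(n_clusters, nrow(uniq)),
                                      nstart = 50))
  pick <- which.max(apply(km$centers, 1, min))
  list(genes = rownames(trajectory_matrix)[km$cluster == pick],
       centroid = km$centers[pick, ], cluster = km$cluster,
       degenerate = FALSE)
}

#' Aggregate-expression confound control
#'
#' Correlates each regional component score with the regional mean of raw
#' expression over all genes, with a permutation p (region labels of the
#' aggregate vector permuted, two-sided on |r|). High correlations would
#' indicate that a component merely tracks overall expression level.
#' A constant aggregate vector (e.g. per-sample-centered data) yields `NA`
#' with a warning.
#'
#' @param model fitted `pls_model`.
#' @param dataset [expression_dataset()] with region labels.
#' @param n_perm,seed permutation settings.
#' @return `data.frame` with `component`, `r`, `p`.
#' @export
aggregate_expression_control <- function(model, dataset, n_perm = 999,
                                         seed = 1) {
  reg <- regional_scores(model, dataset)
  agg_s <- rowMeans(dataset$expression)
  agg <- tapply(agg_s, dataset$region, mean)[reg$ids]
  k <- ncol(reg$scores)
  if (stats::sd(agg) <= 1e-10 * (stats::sd(dataset$expression) + 1e-300)) {
    warning("aggregate regional expression is constant; r undefined")
    return(data.frame(component = seq_len(k), r = NA_real_, p = NA_real_))
  }
  r <- as.vector(stats::cor(reg$scores, agg))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      as.vector(stats::cor(reg$scores, agg[sample.int(length(agg))]))
    }, numeric(k))
  })
  null <- matrix(null, nrow = k)
  p <- vapply(seq_len(k), function(j) {
    perm_pvalue(sum(abs(null[j, ]) >= abs(r[j])), n_perm)
  }, numeric(1))
  data.frame(component = seq_len(k), r = r, p = p)
}
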