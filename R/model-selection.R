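#' Split a dataset into training and test sets
#'
#' Optionally stratified by region (per-region training proportion within
#' one sample of the target); a region with a single sample is assigned to
#' the training set with a warning.
#'
#' @param dataset an [expression_dataset()].
#' @param train_frac training fraction in (0, 1), default 0.7.
#' @param stratify_by_region stratify the split within regions.
#' @param seed RNG seed.
#' @return list with `train` and `test` datasets (disjoint, exhaustive).
#' @export
split_train_test <- function(dataset, train_frac = 0.7,
                             stratify_by_region = FALSE, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  n <- length(dataset$sample_ids)
  idx_train <- with_seed(seed, {
    if (!stratify_by_region) {
      sample.int(n, round(train_frac * n))
    } else {
      unlist(lapply(split(seq_len(n), dataset$region), function(ix) {
        if (length(ix) == 1L) {
          warning("region with a single sample assigned to training set")
          return(ix)
        }
        sample(ix, round(train_frac * length(ix)))
      }), use.names = FALSE)
    }
  })
  list(train = ds_subset(dataset, samples = sort(idx_train)),
       test = ds_subset(dataset, samples = sort(setdiff(seq_len(n), idx_train))))
}

#' Select the number of PLS components by repeated cross-validation
#'
#' For each candidate k the held-out mean Euclidean prediction error (mm) is
#' averaged over `folds x repeats`; the default rule picks the smallest k
#' whose mean error is within one standard error of the minimum (`argmin`
#' available by `rule`). Nested-model coefficients are derived from a single
#' k_max fit per fold, so the error curve is computed consistently.
#'
#' @param train training [expression_dataset()] with coordinates.
#' @param k_max largest k considered (<= 3).
#' @param folds number of CV folds (>= 2).
#' @param repeats number of repeated fold assignments.
#' @param seed RNG seed.
#' @param rule `"one_se"` (default) or `"argmin"`.
#' @param block_by_region assign whole regions to folds, probing spatial
#'   leakage from neighboring samples.
#' @return object of class `cv_result`: `k_grid`, `mean_error`, `se_error`
#'   (mm), `chosen_k`, `errors` (folds*repeats x k matrix), `folds`,
#'   `repeats`, `seed`, `rule`.
#' @export
crossval_component_selection <- function(train, k_max = 3, folds = 10,
                                         repeats = 10, seed = 1,
                                         rule = c("one_se", "argmin"),
                                         block_by_region = FALSE) {
  rule <- match.arg(rule)
  stopifnot(folds >= 2, k_max >= 1, k_max <= 3)
  n <- length(train$sample_ids)
  if (n < folds) stop("fewer training samples (", n, ") than folds (", folds, ")")
  errs <- with_seed(seed, {
    out <- matrix(NA_real_, folds * repeats, k_max)
    row <- 0L
    for (rep_i in seq_len(repeats)) {
      fold_id <- if (block_by_region) {
        regs <- unique(train$region)
        reg_fold <- sample(rep_len(seq_len(folds), length(regs)))
        reg_fold[match(train$region, regs)]
      } else {
        sample(rep_len(seq_len(folds), n))
      }
      for (f in seq_len(folds)) {
        held <- fold_id == f
        if (!any(held) || all(held)) next
        fit <- fit_pls(ds_subset(train, samples = which(!held)), k = k_max,
                       strict = FALSE)
        test_ds <- ds_subset(train, samples = which(held))
        x <- standardize_for_model(fit, test_ds)
        row <- row + 1L
        for (kk in seq_len(k_max)) {
          # rank-deficient folds: k beyond the extractable count adds nothing
          pred <- sweep(x %*% coef_for_k(fit, min(kk, fit$k)), 2,
                        fit$coord_mean, "+")
          out[row, kk] <- mean(sqrt(rowSums((test_ds$coords - pred)^2)))
        }
      }
    }
    out[seq_len(row), , drop = FALSE]
  })
  mean_error <- colMeans(errs)
  se_error <- apply(errs, 2, stats::sd) / sqrt(nrow(errs))
  chosen_k <- if (rule == "argmin") {
    which.min(mean_error)
  } else {
    i_min <- which.min(mean_error)
    min(which(mean_error <= mean_error[i_min] + se_error[i_min]))
  }
  structure(list(k_grid = seq_len(k_max), mean_error = mean_error,
                 se_error = se_error, chosen_k = as.integer(chosen_k),
                 errors = errs, folds = folds, repeats = repeats,
                 seed = seed, rule = rule),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", x$folds, "-fold x ", x$repeats, " repeats, rule ",
      x$rule, ")\n", sep = "")
  print(data.frame(k = x$k_grid, mean_error_mm = signif(x$mean_error, 4),
                   se_mm = signif(x$se_error, 3)), row.names = FALSE)
  cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

# |cosine| similarity between two weight matrices after optimal pairing,
# aligned on shared gene ids.
weight_similarity <- function(w_ref, w_new) {
  common <- intersect(rownames(w_ref), rownames(w_new))
  a <- w_ref[common, , drop = FALSE]
  b <- w_new[common, , drop = FALSE]
  cosm <- crossprod(a, b) /
    outer(sqrt(colSums(a^2)), sqrt(colSums(b^2)))
  pr <- pair_components(cosm)
  pr$abs_r
}

#' Stability of gradient weights under spatial permutation
#'
#' Null model: permute coordinate rows relative to expression rows (identity
#' permutation excluded), refit, and record the |cosine similarity| between
#' each null weight column and the observed weight column after optimal
#' component pairing. The observed statistic per component is the split-half
#' weight similarity of the unpermuted fit (two seeded half-sample fits,
#' each paired to the full fit). `p = (1 + #{null >= observed}) / (n_perm + 1)`,
#' so p-values are always in (0, 1].
#'
#' @param dataset an [expression_dataset()] with coordinates.
#' @param k number of components.
#' @param n_perm number of spatial permutations (>= 1).
#' @param seed RNG seed.
#' @return object of class `stability_result`: `observed_similarity` (k),
#'   `null_similarities` (n_perm x k), `p` (k).
#' @export
spatial_permutation_stability <- function(dataset, k = 3, n_perm = 99,
                                          seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  full <- fit_pls(dataset, k = k)
  n <- length(dataset$sample_ids)
  res <- with_seed(seed, {
    half <- sample.int(n, floor(n / 2))
    fit_a <- fit_pls(ds_subset(dataset, samples = sort(half)), k = k)
    fit_b <- fit_pls(ds_subset(dataset, samples = sort(setdiff(seq_len(n), half))),
                     k = k)
    # Align each half fit's components to the full fit before comparing halves.
    align_to_full <- function(fit) {
      common <- intersect(rownames(full$W), rownames(fit$W))
      cosm <- crossprod(full$W[common, , drop = FALSE],
                        fit$W[common, , drop = FALSE])
      cosm <- cosm / outer(sqrt(colSums(full$W[common, , drop = FALSE]^2)),
                           sqrt(colSums(fit$W[common, , drop = FALSE]^2)))
      pr <- pair_components(cosm)
      fit$W[, pr$order, drop = FALSE]
    }
    wa <- align_to_full(fit_a)
    wb <- align_to_full(fit_b)
    observed <- abs(colSums(wa * wb) /
                      (sqrt(colSums(wa^2)) * sqrt(colSums(wb^2))))
    nulls <- matrix(NA_real_, n_perm, k)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      while (all(perm == seq_len(n))) perm <- sample.int(n)
      ds_p <- dataset
      ds_p$coords <- dataset$coords[perm, , drop = FALSE]
      rownames(ds_p$coords) <- dataset$sample_ids
      fit_p <- fit_pls(ds_p, k = k)
      nulls[b, ] <- weight_similarity(full$W, fit_p$W)
    }
    list(observed = observed, nulls = nulls)
  })
  p <- vapply(seq_len(k), function(j) {
    perm_pvalue(sum(res$nulls[, j] >= res$observed[j]), n_perm)
  }, numeric(1))
  structure(list(observed_similarity = res$observed,
                 null_similarities = res$nulls, p = p, n_perm = n_perm),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability_result (", x$n_perm, " spatial permutations)\n", sep = "")
  print(data.frame(component = seq_along(x$p),
                   split_half_similarity = signif(x$observed_similarity, 3),
                   p = signif(x$p, 3)), row.names = FALSE)
  invisible(x)
}
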