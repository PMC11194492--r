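#' Interpolate sample scores to a cortical surface
#'
#' Inverse-distance weighting over the `k_neighbors` nearest samples in
#' anatomical space. A vertex coinciding with a sample (< 1e-9 mm) takes
#' that sample's value exactly; vertices farther than `max_dist` from every
#' sample, and medial-mask vertices, are missing (`NA`). The number of
#' unreachable vertices is reported via `message()`.
#'
#' @param sample_scores numeric `n_samples x k` matrix (or
#'   [gradient_scores()]).
#' @param sample_coords `n_samples x 3` mm coordinates.
#' @param surface a [surface_pair()].
#' @param k_neighbors neighbors used per vertex (default 10).
#' @param power IDW exponent (default 2).
#' @param max_dist mm cutoff beyond which a vertex is unsampled (default 20).
#' @return `n_vertices x k` matrix of interpolated values (`NA` where
#'   masked/unsampled).
#' @export
interpolate_to_surface <- function(sample_scores, sample_coords, surface,
                                   k_neighbors = 10, power = 2,
                                   max_dist = 20) {
  if (inherits(sample_scores, "gradient_scores")) {
    sample_scores <- sample_scores$scores
  }
  sample_scores <- as.matrix(sample_scores)
  sample_coords <- as.matrix(sample_coords)
  stopifnot(nrow(sample_scores) == nrow(sample_coords),
            nrow(sample_scores) >= 1, k_neighbors >= 1)
  v <- surface$anat_vertices
  nv <- nrow(v)
  out <- matrix(NA_real_, nv, ncol(sample_scores))
  colnames(out) <- colnames(sample_scores)
  kk <- min(k_neighbors, nrow(sample_coords))
  n_unreach <- 0L
  d2 <- outer(rowSums(v^2), rep(1, nrow(sample_coords))) +
    outer(rep(1, nv), rowSums(sample_coords^2)) -
    2 * v %*% t(sample_coords)
  d2[d2 < 0] <- 0
  for (i in seq_len(nv)) {
    if (surface$medial_mask[i]) next
    d <- sqrt(d2[i, ])
    if (min(d) > max_dist) {
      n_unreach <- n_unreach + 1L
      next
    }
    nb <- order(d)[seq_len(kk)]
    if (d[nb[1]] < 1e-9) {
      out[i, ] <- sample_scores[nb[1], ]
    } else {
      w <- 1 / d[nb]^power
      out[i, ] <- colSums(sample_scores[nb, , drop = FALSE] * w) / sum(w)
    }
  }
  if (n_unreach > 0) {
    message("interpolate_to_surface: ", n_unreach,
            " vertex(es) farther than ", max_dist, " mm from any sample")
  }
  out
}

#' Cluster cortical vertices into molecular territories
#'
#' k-means (`nstart = 50`, seeded) on per-vertex z-scored component values.
#' When `k` is `NULL` the number of territories is selected by mean
#' silhouette width over `k_range`. Vertices with any missing component are
#' labeled 0 (unassigned).
#'
#' @param lv_fields `n_vertices x m` matrix of component values (m >= 2
#'   columns; typically the three interpolated gradients).
#' @param k number of territories, or `NULL` for silhouette selection.
#' @param seed RNG seed.
#' @param k_range candidate k values for silhouette selection.
#' @return object of class `territory_labels`: integer `labels` per vertex
#'   (0 = unassigned), `k`, and (when selected) the `silhouette` table.
#' @export
cluster_territories <- function(lv_fields, k = NULL, seed = 1, k_range = 2:10) {
  lv_fields <- as.matrix(lv_fields)
  if (ncol(lv_fields) < 2) stop("need at least 2 component fields")
  ok <- stats::complete.cases(lv_fields)
  if (!any(ok)) stop("all vertices missing")
  z <- scale(lv_fields[ok, , drop = FALSE])
  sil_tab <- NULL
  if (is.null(k)) {
    dmat <- stats::dist(z)
    sil <- vapply(k_range, function(kk) {
      cl <- with_seed(seed, stats::kmeans(z, centers = kk, nstart = 50))
      mean(cluster::silhouette(cl$cluster, dmat)[, 3])
    }, numeric(1))
    sil_tab <- data.frame(k = k_range, mean_silhouette = sil)
    k <- k_range[which.max(sil)]
  }
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = 50))
  labels <- integer(nrow(lv_fields))
  labels[ok] <- km$cluster
  structure(list(labels = labels, k = as.integer(k), silhouette = sil_tab),
            class = "territory_labels")
}

#' @export
print.territory_labels <- function(x, ...) {
  cat("territory_labels:", x$k, "territories over", length(x$labels),
      "vertices (", sum(x$labels == 0), "unassigned )\n")
  invisible(x)
}

# ---- partition agreement -----------------------------------------------------

ari_from_contingency <- function(tab) {
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(0)
  (sum_ij - expected) / denom
}

entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

mi_from_contingency <- function(tab) {
  n <- sum(tab)
  mi <- 0
  rs <- unname(rowSums(tab)); cs <- unname(colSums(tab))
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (rs[i] * cs[j]))
    }
  }
  mi
}

# Expected mutual information under the permutation (hypergeometric) model.
emi_from_margins <- function(rs, cs, n) {
  emi <- 0
  for (i in seq_along(rs)) {
    ai <- rs[i]
    for (j in seq_along(cs)) {
      bj <- cs[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      for (nij in lo:hi) {
        lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
          lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
          lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
          lgamma(n - ai - bj + nij + 1)
        emi <- emi + exp(lp) * (nij / n) * log(n * nij / (ai * bj))
      }
    }
  }
  emi
}

ami_from_contingency <- function(tab) {
  n <- sum(tab)
  rs <- unname(rowSums(tab)); cs <- unname(colSums(tab))
  mi <- mi_from_contingency(tab)
  emi <- emi_from_margins(rs, cs, n)
  h_mean <- (entropy_counts(rs) + entropy_counts(cs)) / 2    # arithmetic norm
  denom <- h_mean - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

#' Compare two parcellations by adjusted Rand index and adjusted mutual information
#'
#' Vertices labeled 0 or `NA` on either side (or masked) are excluded
#' pairwise. ARI uses the permutation-model adjusted formula from the
#' contingency table; AMI uses the hypergeometric expected mutual
#' information with arithmetic-mean entropy normalization.
#'
#' @param labels_a,labels_b integer label vectors (0 = unassigned) or
#'   `territory_labels` objects.
#' @param mask optional logical; `TRUE` vertices are excluded.
#' @return list with `ami`, `ari`, and `n` (vertices compared).
#' @export
compare_parcellations <- function(labels_a, labels_b, mask = NULL) {
  if (inherits(labels_a, "territory_labels")) labels_a <- labels_a$labels
  if (inherits(labels_b, "territory_labels")) labels_b <- labels_b$labels
  stopifnot(length(labels_a) == length(labels_b))
  keep <- !is.na(labels_a) & !is.na(labels_b) & labels_a != 0 & labels_b != 0
  if (!is.null(mask)) keep <- keep & !mask
  a <- labels_a[keep]; b <- labels_b[keep]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop("need at least 2 labels on each side after exclusions")
  }
  tab <- table(a, b)
  list(ami = ami_from_contingency(tab), ari = ari_from_contingency(tab),
       n = length(a))
}

# ---- spin permutations -------------------------------------------------------

# Vertex reassignment index for one rotation: vertex v takes the value of the
# original vertex nearest to the rotated position of v.
spin_index <- function(sphere_vertices, rotation) {
  rotated <- sphere_vertices %*% t(rotation)
  max.col(rotated %*% t(sphere_vertices), ties.method = "first")
}

#' Spin permutations of a spherical surface
#'
#' Each permutation draws a uniform random 3D rotation (orthonormalized
#' Gaussian with determinant fix), rotates the sphere vertices, and reassigns
#' each vertex the value of the nearest original vertex. Returned as an
#' index matrix so the same spins can be applied to maps and to label fields;
#' masked vertices propagate missing values downstream.
#'
#' @param surface a [surface_pair()].
#' @param n_perm number of spins (>= 1).
#' @param seed RNG seed.
#' @return integer `n_vertices x n_perm` matrix `idx`; the spun field is
#'   `values[idx[, b]]`.
#' @export
spin_permutation <- function(surface, n_perm, seed = 1) {
  stopifnot(inherits(surface, "surface_pair"), n_perm >= 1)
  sph <- surface$sphere_vertices
  with_seed(seed, {
    idx <- matrix(0L, nrow(sph), n_perm)
    for (b in seq_len(n_perm)) {
      idx[, b] <- spin_index(sph, random_rotation())
    }
    idx
  })
}

#' Apply a spin index to a per-vertex field
#'
#' @param values per-vertex vector (`NA` allowed; propagates).
#' @param idx one column of [spin_permutation()]'s index matrix.
#' @return the spun field.
#' @export
apply_spin <- function(values, idx) values[idx]

#' Correlation between two surface maps with a spin-test p-value
#'
#' Pearson r over common non-missing vertices; two-sided p with the add-one
#' formula against spins of `field_a`.
#'
#' @param field_a,field_b per-vertex numeric vectors.
#' @param surface a [surface_pair()].
#' @param n_perm number of spins.
#' @param seed RNG seed.
#' @return list with `r`, `p_spin`, `null_r`, `n` (vertices used).
#' @export
map_correlation_with_spin_null <- function(field_a, field_b, surface,
                                           n_perm = 1000, seed = 1) {
  stopifnot(length(field_a) == length(field_b))
  ok <- !is.na(field_a) & !is.na(field_b) & !surface$medial_mask
  if (sum(ok) < 10) stop("fewer than 10 common non-missing vertices")
  r <- stats::cor(field_a[ok], field_b[ok])
  idx <- spin_permutation(surface, n_perm, seed = seed)
  null_r <- vapply(seq_len(n_perm), function(b) {
    fa <- apply_spin(field_a, idx[, b])
    use <- !is.na(fa) & !is.na(field_b) & !surface$medial_mask
    stats::cor(fa[use], field_b[use])
  }, numeric(1))
  p <- perm_pvalue(sum(abs(null_r) >= abs(r)), n_perm)
  list(r = r, p_spin = p, null_r = null_r, n = sum(ok))
}

# ---- bootstrapped model comparison ------------------------------------------

r2_ols <- function(y, x) {
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  n <- length(y)
  p <- fit$rank - 1L
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  c(r2 = r2, adj = adj)
}

#' Compare variance explained by two predictor sets with bootstrap
#'
#' Ordinary least squares with intercept for model A (`set_a`), model B
#' (`set_b`) and the combined model (union of predictors); total R2 each,
#' with percentile-bootstrap CIs over units. `p_diff` is the two-sided
#' bootstrap p for `R2_A - R2_B`. `p_combined_gain` is the one-sided
#' bootstrap p for a positive combined-model gain computed on *adjusted* R2
#' (`adjR2_combined - max(adjR2_A, adjR2_B)`): the raw-R2 gain of a nested
#' model is non-negative by construction, so only the
#' degrees-of-freedom-adjusted gain is a testable quantity. Collinear
#' combined predictors are fitted by pivoted least squares (equivalent to
#' the pseudoinverse fit) with a warning.
#'
#' @param feature numeric response per unit (parcel or vertex).
#' @param set_a,set_b numeric matrices `n_units x p` of predictor maps.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return object of class `model_comparison`: point estimates `r2_a`,
#'   `r2_b`, `r2_combined`, percentile `ci` per quantity, `p_diff`,
#'   `p_combined_gain`, `n_units`.
#' @export
feature_variance_models <- function(feature, set_a, set_b, n_boot = 1000,
                                    seed = 1) {
  set_a <- as.matrix(set_a); set_b <- as.matrix(set_b)
  y <- as.numeric(feature)
  n <- length(y)
  stopifnot(nrow(set_a) == n, nrow(set_b) == n)
  p_tot <- ncol(set_a) + ncol(set_b)
  if (n < p_tot + 10) stop("need at least predictors + 10 units")
  comb <- cbind(set_a, set_b)
  if (qr(cbind(1, comb))$rank < ncol(comb) + 1) {
    warning("collinear predictors in the combined model; ",
            "fitting by pivoted least squares")
  }
  point_a <- r2_ols(y, set_a); point_b <- r2_ols(y, set_b)
  point_c <- r2_ols(y, comb)
  boot <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      c(r2_ols(y[i], set_a[i, , drop = FALSE]),
        r2_ols(y[i], set_b[i, , drop = FALSE]),
        r2_ols(y[i], comb[i, , drop = FALSE]))
    }, numeric(6)))
  })
  colnames(boot) <- c("a", "a_adj", "b", "b_adj", "combined", "combined_adj")
  ci <- apply(boot[, c("a", "b", "combined")], 2, stats::quantile,
              probs = c(0.025, 0.975))
  d <- boot[, "a"] - boot[, "b"]
  p_diff <- min(1, 2 * min(perm_pvalue(sum(d <= 0), n_boot),
                           perm_pvalue(sum(d >= 0), n_boot)))
  gain <- boot[, "combined_adj"] - pmax(boot[, "a_adj"], boot[, "b_adj"])
  p_gain <- perm_pvalue(sum(gain <= 0), n_boot)
  structure(list(r2_a = unname(point_a["r2"]), r2_b = unname(point_b["r2"]),
                 r2_combined = unname(point_c["r2"]),
                 ci = ci, p_diff = p_diff, p_combined_gain = p_gain,
                 n_units = n, n_boot = n_boot, boot = boot),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model_comparison over", x$n_units, "units (", x$n_boot,
      "bootstrap resamples)\n")
  cat(sprintf("  R2_A = %.3f [%.3f, %.3f]\n", x$r2_a,
              x$ci[1, "a"], x$ci[2, "a"]))
  cat(sprintf("  R2_B = %.3f [%.3f, %.3f]\n", x$r2_b,
              x$ci[1, "b"], x$ci[2, "b"]))
  cat(sprintf("  R2_combined = %.3f [%.3f, %.3f]\n", x$r2_combined,
              x$ci[1, "combined"], x$ci[2, "combined"]))
  cat(sprintf("  p_diff = %.4g, p_combined_gain = %.4g\n",
              x$p_diff, x$p_combined_gain))
  invisible(x)
}
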