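# Shared fixtures and independent oracles, all generated in code.

# Small random dataset with coordinates (optionally regions).
tiny_dataset <- function(n = 30, g = 12, seed = 1, n_regions = NULL) {
  set.seed(seed)
  coords <- matrix(runif(n * 3, -50, 50), n, 3)
  expr <- matrix(rnorm(n * g), n, g)
  colnames(expr) <- sprintf("g%05d", seq_len(g))
  region <- if (!is.null(n_regions)) {
    sprintf("region%02d", rep_len(seq_len(n_regions), n))
  }
  expression_dataset(expr, coords = coords, region = region)
}

# Independent PLS oracle: per-step dense SVD of the explicitly deflated
# cross-covariance. Shares no code with fit_pls (svd vs 3x3 eigen route).
pls_svd_oracle <- function(expr, coords, k) {
  x <- scale(expr)
  y <- scale(coords, scale = FALSE)
  W <- matrix(0, ncol(x), k)
  for (j in seq_len(k)) {
    sv <- svd(crossprod(x, y))
    w <- sv$u[, 1]
    t_ <- as.vector(x %*% w)
    p <- as.vector(crossprod(x, t_)) / sum(t_^2)
    W[, j] <- w
    x <- x - tcrossprod(t_, p)
  }
  W
}

# Distance between unit vectors up to sign.
sign_free_dist <- function(a, b) min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))

# Brute-force pair-counting adjusted Rand index (independent of the
# contingency-table implementation).
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  tot <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(0)
  (n11 - expected) / (maxi - expected)
}

# Exhaustive expected mutual information under the permutation model:
# average MI over all n! relabelings of one partition (n <= 7).
emi_enumeration_oracle <- function(a, b) {
  n <- length(a)
  perms <- spatiomol:::all_perms(n)
  mean(apply(perms, 1, function(p) {
    spatiomol:::mi_from_contingency(table(a[p], b))
  }))
}

# Mutual information / entropy direct from label vectors (plug-in).
mi_plugin <- function(a, b) spatiomol:::mi_from_contingency(table(a, b))

# Planted-gradient discovery study at reduced size (for fast tests).
small_study <- function(n = 400, g = 400, seed = 1, noise_sd = 1,
                        isotropic = TRUE) {
  axes <- if (isotropic) c(75, 75, 75) else c(70, 85, 65)
  coords <- generate_brain_cloud(n, semi_axes_mm = axes, seed = seed)
  plant_gradients(coords, n_genes = g, k_true = 3, noise_sd = noise_sd,
                  seed = seed)
}
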