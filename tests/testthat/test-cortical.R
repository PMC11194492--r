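test_that("surface interpolation honors exact hits, constants, and linear fields", {
  fx <- make_surface_fixture(162, seed = 50)
  surf <- fx$surface
  # samples at a subset of vertex positions: those vertices take sample values
  idx <- seq(1, 160, by = 4)
  coords <- surf$anat_vertices[idx, ]
  vals <- cbind(rnorm(length(idx)))
  out <- interpolate_to_surface(vals, coords, surf, k_neighbors = 5,
                                max_dist = 1e9)
  expect_equal(out[idx, 1], vals[, 1], tolerance = 1e-12)
  # constant field stays constant everywhere reachable
  outc <- interpolate_to_surface(matrix(7, length(idx), 1), coords, surf,
                                 max_dist = 1e9)
  expect_true(all(abs(outc - 7) < 1e-12))
  # dense sampling of a linear field reproduces it within 5% of its range:
  # samples drawn in a thin shell around the surface so every vertex has a
  # well-balanced neighborhood
  set.seed(51)
  dirs <- matrix(rnorm(4000 * 3), 4000, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  dense <- sweep(dirs, 2, c(70, 85, 65), "*") * runif(4000, 0.93, 1.07)
  lin <- dense %*% c(0.5, -0.3, 0.2)
  outl <- interpolate_to_surface(cbind(lin), dense, fx$surface,
                                 k_neighbors = 10, max_dist = 30)
  true_l <- surf$anat_vertices %*% c(0.5, -0.3, 0.2)
  ok <- !is.na(outl[, 1])
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(outl[ok, 1] - true_l[ok])), 0.05 * diff(range(true_l)))
  # unreachable vertices are missing and counted
  expect_message(
    far <- interpolate_to_surface(vals, coords / 10, surf, max_dist = 20),
    "farther than")
  expect_true(anyNA(far))
})

test_that("territory clustering recovers separable structure deterministically", {
  set.seed(52)
  blob <- rbind(matrix(rnorm(300, mean = 0, sd = 0.3), 100, 3),
                matrix(rnorm(300, mean = 5, sd = 0.3), 100, 3))
  t1 <- cluster_territories(blob, k = 2, seed = 1)
  truth <- rep(1:2, each = 100)
  expect_equal(compare_parcellations(t1$labels, truth)$ari, 1)
  t2 <- cluster_territories(blob, k = 2, seed = 1)
  expect_identical(t1$labels, t2$labels)
  # missing vertices are labeled 0
  blob_na <- blob; blob_na[3, 1] <- NA
  t3 <- cluster_territories(blob_na, k = 2, seed = 1)
  expect_equal(t3$labels[3], 0L)
  expect_error(cluster_territories(matrix(NA_real_, 5, 3), k = 2), "missing")
})

test_that("silhouette selection finds six planted territories", {
  # six well-separated centers in 3-component space (sign-octant style)
  set.seed(53)
  centers <- rbind(c(1, 1, 1), c(-1, -1, -1), c(1, -1, 1), c(-1, 1, 1),
                   c(1, 1, -1), c(-1, -1, 1)) * 3
  fields <- centers[rep(1:6, each = 80), ] + matrix(rnorm(480 * 3, sd = 0.4),
                                                    480, 3)
  res <- cluster_territories(fields, k = NULL, seed = 2, k_range = 2:9)
  expect_equal(res$k, 6L)
  expect_equal(compare_parcellations(res$labels, rep(1:6, each = 80))$ari, 1)
})

test_that("ARI and AMI match hand values and brute-force oracles", {
  # the classic crossed partition: ARI is exactly -0.5
  x <- compare_parcellations(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(x$ari, -0.5, tolerance = 1e-12)
  ident <- compare_parcellations(c(1, 1, 2, 2, 3), c(5, 5, 7, 7, 9))
  expect_equal(ident$ari, 1)
  expect_equal(ident$ami, 1, tolerance = 1e-12)
  # random partitions of <= 12 items vs the exhaustive pair-counting oracle
  set.seed(54)
  for (case in 1:40) {
    n <- sample(5:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(compare_parcellations(a, b)$ari, ari_pair_oracle(a, b),
                 tolerance = 1e-12)
  }
  # AMI expected-MI term vs exhaustive enumeration over all n! relabelings
  set.seed(55)
  for (case in 1:5) {
    n <- sample(5:7, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    tab <- table(a, b)
    emi <- spatiomol:::emi_from_margins(unname(rowSums(tab)),
                                        unname(colSums(tab)), n)
    expect_equal(emi, emi_enumeration_oracle(a, b), tolerance = 1e-10)
  }
  # independent random labelings on many items are chance-level
  set.seed(56)
  a <- sample(1:5, 10000, replace = TRUE)
  b <- sample(1:6, 10000, replace = TRUE)
  big <- compare_parcellations(a, b)
  expect_lt(abs(big$ari), 0.02)
  expect_lt(abs(big$ami), 0.02)
})

test_that("ARI agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(57)
  for (case in 1:10) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(compare_parcellations(a, b)$ari,
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("spin permutations are rotations with value-set preservation", {
  fx <- make_surface_fixture(162, smooth_iter = 10, seed = 58)
  sph <- fx$surface$sphere_vertices
  # identity rotation maps every vertex to itself
  expect_identical(spatiomol:::spin_index(sph, diag(3)), seq_len(nrow(sph)))
  # an exact icosahedral symmetry (72 degrees about a vertex axis) permutes
  # the icosphere onto itself: the spin is then a bijection
  axis <- sph[1, ]
  th <- 2 * pi / 5
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R72 <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  idx72 <- spatiomol:::spin_index(sph, R72)
  expect_setequal(idx72, seq_len(nrow(sph)))     # a permutation
  expect_identical(sort(fx$maps[idx72, 1]), sort(fx$maps[, 1]))
  # generic spins only reassign existing values
  idx <- spin_permutation(fx$surface, n_perm = 5, seed = 3)
  for (b in 1:5) {
    expect_true(all(fx$maps[idx[, b], 1] %in% fx$maps[, 1]))
  }
  expect_identical(spin_permutation(fx$surface, 5, seed = 3), idx)
})

test_that("spin-null map correlation has the expected trivial behavior", {
  fx <- make_surface_fixture(162, smooth_iter = 10, n_maps = 2, seed = 59)
  a <- fx$maps[, 1]
  self <- map_correlation_with_spin_null(a, a, fx$surface, n_perm = 99,
                                         seed = 4)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$p_spin, 1 / 100)
  neg <- map_correlation_with_spin_null(a, -a, fx$surface, n_perm = 99,
                                        seed = 4)
  expect_equal(neg$r, -1, tolerance = 1e-12)
  expect_equal(neg$p_spin, 1 / 100)
})

test_that("bootstrapped model comparison orders nested models correctly", {
  set.seed(60)
  n <- 360
  set_a <- matrix(rnorm(n * 3), n, 3)
  set_b <- matrix(rnorm(n * 3), n, 3)
  # feature equal to one set-A map
  res <- feature_variance_models(set_a[, 1], set_a, set_b, n_boot = 200,
                                 seed = 5)
  expect_equal(res$r2_a, 1, tolerance = 1e-10)
  expect_equal(res$r2_combined, 1, tolerance = 1e-10)
  expect_lt(res$p_diff, 0.05)
  expect_gte(res$r2_combined, max(res$r2_a, res$r2_b) - 1e-10)
  # independent noise feature: all R2 small, no stars
  noise <- rnorm(n)
  res0 <- feature_variance_models(noise, set_a, set_b, n_boot = 200, seed = 6)
  expect_lt(res0$r2_a, 0.05)
  expect_lt(res0$r2_b, 0.05)
  expect_gt(res0$p_diff, 0.05)
  expect_gt(res0$p_combined_gain, 0.05)
  # collinear combined predictors warn but still fit
  expect_warning(feature_variance_models(noise, set_a,
                                         set_a[, c(1, 2, 3)], n_boot = 50,
                                         seed = 7),
                 "collinear")
})
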