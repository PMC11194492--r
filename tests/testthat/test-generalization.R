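# Shared discovery study for generalization tests (built once per run).
disc_env <- new.env()
get_discovery <- function() {
  if (is.null(disc_env$sim)) {
    coords <- generate_brain_cloud(800, seed = 40)
    disc_env$sim <- plant_gradients(coords, 600, k_true = 3, seed = 40)
    disc_env$fit <- fit_pls(disc_env$sim$dataset, 3)
    disc_env$cent <- make_region_centroids(16, seed = 41)
  }
  disc_env
}

test_that("refitting on the full gene set reproduces the full model", {
  d <- get_discovery()
  re <- refit_on_shared_genes(d$sim$dataset, d$sim$dataset$gene_ids, k = 3,
                              full_model = d$fit)
  expect_equal(re$W, d$fit$W, tolerance = 1e-10)
  expect_identical(re$alignment$order, 1:3)
})

test_that("refitting on a gene subset preserves the latent structure", {
  coords <- generate_brain_cloud(400, seed = 42)
  sim <- plant_gradients(coords, 400, k_true = 3, frac_gradient_genes = 1,
                         noise_sd = 0, seed = 42)
  full <- fit_pls(sim$dataset, 3)
  set.seed(43)
  half <- sample(sim$dataset$gene_ids, 200)
  re <- refit_on_shared_genes(sim$dataset, half, k = 3, full_model = full)
  r <- abs(diag(cor(re$U, full$U)))
  expect_true(all(r > 0.99))
  expect_error(refit_on_shared_genes(sim$dataset, sim$dataset$gene_ids[1:10]),
               "10 shared")
})

test_that("gene-id mapping tables translate external ids before intersecting", {
  d <- get_discovery()
  ext_ids <- paste0("mouse_", d$sim$dataset$gene_ids[1:300])
  mapping <- data.frame(external = ext_ids,
                        discovery = d$sim$dataset$gene_ids[1:300])
  re <- refit_on_shared_genes(d$sim$dataset, ext_ids, k = 3,
                              mapping = mapping, full_model = d$fit)
  expect_setequal(re$gene_ids, d$sim$dataset$gene_ids[1:300])
})

test_that("regional scores are within-region means of sample scores", {
  d <- get_discovery()
  ds <- d$sim$dataset
  ds$region <- sprintf("region%02d", rep_len(1:8, length(ds$sample_ids)))
  sc <- transform_scores(d$fit, ds)
  reg <- regional_scores(d$fit, ds)
  # hand-computed mean for two regions
  for (rg in c("region01", "region05")) {
    expect_equal(reg$scores[rg, ],
                 colMeans(sc$scores[ds$region == rg, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # one sample per region: regional scores equal sample scores
  one <- ds_subset(ds, samples = 1:8)
  one$region <- sprintf("r%02d", 1:8)
  reg1 <- regional_scores(d$fit, one)
  expect_equal(unname(reg1$scores[sprintf("r%02d", 1:8), ]),
               unname(transform_scores(d$fit, one)$scores), tolerance = 1e-12)
})

test_that("regional similarity has the expected trivial and null behavior", {
  set.seed(44)
  sc <- matrix(rnorm(30), 10, 3)
  ids <- sprintf("r%02d", 1:10)
  a <- gradient_scores(ids, sc, level = "region")
  same <- regional_similarity(a, a, n_perm = 99, seed = 1)
  expect_equal(unname(unlist(same[paste0("r_LV", 1:3)])), c(1, 1, 1),
               tolerance = 1e-12)
  expect_equal(unname(unlist(same[paste0("p_LV", 1:3)])), rep(1 / 100, 3))
  neg <- gradient_scores(ids, -sc, level = "region")
  opp <- regional_similarity(a, neg, n_perm = 99, seed = 1)
  expect_equal(unname(unlist(opp[paste0("r_LV", 1:3)])), c(-1, -1, -1),
               tolerance = 1e-12)
  expect_true(all(unlist(opp[paste0("p_LV", 1:3)]) > 0.9))
  # exact enumeration path for small panels: p bounded below by 1/n!
  small_a <- gradient_scores(ids[1:5], sc[1:5, , drop = FALSE], "region")
  ex <- regional_similarity(small_a, small_a, seed = 1)
  expect_equal(ex$p_LV1, 1 / factorial(5), tolerance = 1e-12)
  expect_error(regional_similarity(small_a,
                                   gradient_scores(c("x", "y", "q"),
                                                   sc[1:3, ], "region")),
               "shared region")
})

test_that("independent replicas from one truth replicate each other's gradients", {
  d <- get_discovery()
  reps <- make_external_replica(d$sim$truth, d$cent, genes_kept_frac = 1,
                                samples_per_region = 4,
                                indiv_noise_sd = d$sim$truth$noise_sd / 2,
                                n_individuals = 2, seed = 45)
  ra <- regional_scores(d$fit, reps[[1]])
  rb <- regional_scores(d$fit, reps[[2]])
  rec <- regional_similarity(ra, rb, n_perm = 199, seed = 2)
  expect_true(all(unlist(rec[paste0("r_LV", 1:3)]) > 0.9))
  expect_true(all(unlist(rec[paste0("p_LV", 1:3)]) <= 0.05))
})

test_that("developmental trajectories track fidelity and skip ageless donors", {
  d <- get_discovery()
  adult_ref_ds <- make_external_replica(d$sim$truth, d$cent,
                                        samples_per_region = 4,
                                        indiv_noise_sd = 0, seed = 46)[[1]]
  adult_ref <- regional_scores(d$fit, adult_ref_ds)
  curves_flat <- replicate(3, fidelity_curve(1, 0, 40), simplify = FALSE)
  ages <- c(10, 30, 100, 900)
  flat <- make_developmental_series(d$sim$truth, d$cent, curves_flat, ages,
                                    noise_sd = 0, seed = 3)
  tr <- developmental_trajectory(d$fit, flat, adult_ref, n_perm = 99, seed = 4)
  expect_true(all(unlist(tr[paste0("r_LV", 1:3)]) > 0.99))
  # a donor without age is skipped with a warning
  noage <- flat
  noage[[2]]$age_pcw <- NULL
  expect_warning(tr2 <- developmental_trajectory(d$fit, noage, adult_ref,
                                                 n_perm = 99, seed = 4),
                 "no age")
  expect_equal(nrow(tr2), 3)
  expect_equal(tr$log_age_pcw, log(ages))
})

test_that("gradient-associated gene selection matches a brute-force oracle", {
  d <- get_discovery()
  ds <- make_external_replica(d$sim$truth, d$cent, samples_per_region = 3,
                              indiv_noise_sd = 0.5, seed = 47)[[1]]
  adult_reg <- regional_scores(d$fit, ds)
  lv1 <- adult_reg$scores[, 1]
  top <- find_gradient_associated_genes(ds, lv1, top_frac = 0.05)
  expect_equal(nrow(top), floor(length(ds$gene_ids) * 0.05))
  # brute-force loop oracle
  rm_ <- rowsum(ds$expression, ds$region)
  rm_ <- rm_ / as.vector(table(ds$region)[rownames(rm_)])
  rm_ <- rm_[names(lv1), ]
  brute <- vapply(seq_len(ncol(rm_)), function(j) {
    if (sd(rm_[, j]) == 0) return(-Inf)
    cor(rm_[, j], lv1)
  }, numeric(1))
  names(brute) <- colnames(rm_)
  brute_top <- names(sort(brute, decreasing = TRUE))[seq_len(nrow(top))]
  expect_setequal(top$gene_id, brute_top)
  # a gene constructed to equal the regional profile is always selected
  ds2 <- ds
  ds2$expression[, 7] <- lv1[ds$region]
  top2 <- find_gradient_associated_genes(ds2, lv1, top_frac = 0.02)
  expect_true(ds2$gene_ids[7] %in% top2$gene_id)
  expect_equal(top2$r[top2$gene_id == ds2$gene_ids[7]], 1, tolerance = 1e-10)
})

test_that("nontransitional gene clustering finds the flat-high archetype", {
  # two archetypes: flat-high vs flat-low
  traj <- rbind(matrix(0.9, 20, 5), matrix(0.1, 30, 5))
  rownames(traj) <- sprintf("g%03d", 1:50)
  res <- nontransitional_genes(traj, n_clusters = 2, seed = 1)
  expect_setequal(res$genes, sprintf("g%03d", 1:20))
  # three archetypes with noise: precision and recall >= 0.9
  set.seed(48)
  ages <- 5
  rise <- t(replicate(40, seq(0.1, 0.9, length.out = ages)))
  fall <- t(replicate(40, seq(0.9, 0.1, length.out = ages)))
  flat <- matrix(0.85, 40, ages)
  traj3 <- rbind(rise, fall, flat) + rnorm(120 * ages, sd = 0.05)
  rownames(traj3) <- sprintf("g%03d", 1:120)
  res3 <- nontransitional_genes(traj3, n_clusters = 3, seed = 2)
  truth_set <- sprintf("g%03d", 81:120)
  precision <- mean(res3$genes %in% truth_set)
  recall <- mean(truth_set %in% res3$genes)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # invariance to gene order
  perm <- sample(120)
  res3p <- nontransitional_genes(traj3[perm, ], n_clusters = 3, seed = 2)
  expect_setequal(res3p$genes, res3$genes)
  # identical trajectories: degenerate flag, no error
  resd <- nontransitional_genes(matrix(0.5, 10, 4), n_clusters = 2, seed = 1)
  expect_true(resd$degenerate)
  expect_length(resd$cluster, 10)
})

test_that("aggregate-expression control flags offsets and handles degenerate aggregates", {
  d <- get_discovery()
  # balance the loadings so the gene-average of the signal is exactly zero
  # ("zero global offset"); random sign imbalance would otherwise couple the
  # aggregate to the planted gradient space
  tr <- d$sim$truth
  for (j in 1:3) {
    on <- tr$gradient_gene_mask[, j]
    tr$gene_loadings[on, j] <- tr$gene_loadings[on, j] -
      mean(tr$gene_loadings[on, j])
  }
  ds <- make_external_replica(tr, d$cent, samples_per_region = 4,
                              indiv_noise_sd = 1, seed = 49)[[1]]
  ctl <- aggregate_expression_control(d$fit, ds, n_perm = 199, seed = 5)
  expect_true(all(abs(ctl$r) <= 0.6))      # null-level at 16 regions
  expect_true(all(ctl$p > 0.05))           # no component flagged
  # per-sample centering makes the aggregate constant
  ds0 <- ds
  ds0$expression <- ds0$expression - rowMeans(ds0$expression)
  expect_warning(ctl0 <- aggregate_expression_control(d$fit, ds0, n_perm = 99),
                 "constant")
  expect_true(all(is.na(ctl0$r)))
})
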