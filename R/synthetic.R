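#' Sample a brain-shaped point cloud
#'
#' Points uniform inside an origin-centered ellipsoid whose semi-axes (mm)
#' approximate a human brain's extents. Uniformity is obtained by rejection
#' sampling from the bounding box.
#'
#' @param n_samples number of points (>= 4).
#' @param semi_axes_mm positive length-3 vector of semi-axes, default
#'   `c(70, 85, 65)` (left-right, posterior-anterior, inferior-superior).
#' @param seed RNG seed.
#' @return `n_samples x 3` matrix of mm coordinates.
#' @export
generate_brain_cloud <- function(n_samples, semi_axes_mm = c(70, 85, 65),
                                 seed = 1) {
  stopifnot(n_samples >= 4, length(semi_axes_mm) == 3, all(semi_axes_mm > 0))
  with_seed(seed, {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n_samples) {
      m <- ceiling((n_samples - nrow(out)) / 0.5)  # ball fills pi/6 of box
      cand <- matrix(stats::runif(3 * m, -1, 1), m, 3)
      cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
      out <- rbind(out, cand)
    }
    out <- out[seq_len(n_samples), , drop = FALSE]
    out <- sweep(out, 2, semi_axes_mm, "*")
    colnames(out) <- c("x", "y", "z")
    out
  })
}

#' Plant orthogonal spatial expression gradients
#'
#' Builds expression that is exactly linear in space before noise:
#' `expression[s, g] = sum_k loadings[g, k] * (direction_k . coords[s]) + eps`,
#' with `eps ~ Normal(0, noise_sd^2)`. The `k_true` planted directions are
#' random orthonormal columns (seeded) so recovery cannot succeed through
#' axis-aligned shortcuts; set `axis_aligned = TRUE` for didactic fixtures.
#' Each gradient recruits a seeded random subset of
#' `frac_gradient_genes` of the genes; non-recruited loadings are exactly 0.
#'
#' When `loading_scale` is `NULL` it is set so that the per-gradient
#' signal-to-noise ratio `loading_scale * sd(projection) / noise_sd` equals
#' `snr` (default 4); the realized SNR per gradient is stored in the truth.
#'
#' @param coords `n x 3` coordinate matrix (see [generate_brain_cloud()]).
#'   For studies whose goal is recovery of the individual planted directions,
#'   use an isotropic cloud (equal semi-axes): anisotropic coordinate
#'   variance pins the within-span rotation of the fitted components to the
#'   cloud's principal axes rather than to the planted directions.
#' @param n_genes number of genes.
#' @param k_true number of planted gradients (<= 3; space is 3-D).
#' @param frac_gradient_genes fraction of genes recruited per gradient;
#'   scalar or one value per gradient, each in (0, 1]. Default `NULL` uses
#'   the graded ladder `c(0.25, 0.15, 0.08)[1:k_true]`: distinct recruitment
#'   sizes give the gradients distinct effective strengths, which is what
#'   makes the individual components identifiable after per-gene
#'   standardization (equal recruitment leaves only their joint span
#'   identifiable).
#' @param loading_scale standard deviation of nonzero gene loadings, or
#'   `NULL` to derive from `snr`.
#' @param noise_sd additive expression noise SD (> 0 unless exactly 0 for
#'   noise-free fixtures).
#' @param snr target per-gradient signal-to-noise ratio used when
#'   `loading_scale` is `NULL`.
#' @param seed RNG seed.
#' @param axis_aligned use the identity directions instead of a random
#'   orthonormal frame.
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (class `synthetic_truth`: `directions` 3 x k_true orthonormal,
#'   `gene_loadings` n_genes x k_true, `gradient_gene_mask`, `noise_sd`,
#'   `loading_scale`, `snr` realized per gradient).
#' @export
plant_gradients <- function(coords, n_genes, k_true = 3,
                            frac_gradient_genes = NULL,
                            loading_scale = NULL, noise_sd = 1, snr = 4,
                            seed = 1, axis_aligned = FALSE) {
  coords <- as.matrix(coords)
  if (k_true > 3) stop("k_true must be <= 3: spatial space is 3-D")
  if (is.null(frac_gradient_genes)) {
    frac_gradient_genes <- c(0.25, 0.15, 0.08)[seq_len(k_true)]
  }
  frac_gradient_genes <- rep_len(frac_gradient_genes, k_true)
  stopifnot(k_true >= 1, all(frac_gradient_genes > 0),
            all(frac_gradient_genes <= 1), noise_sd >= 0)
  n <- nrow(coords)
  with_seed(seed, {
    if (axis_aligned) {
      directions <- diag(3)[, seq_len(k_true), drop = FALSE]
    } else {
      directions <- qr.Q(qr(matrix(stats::rnorm(9), 3)))[, seq_len(k_true),
                                                         drop = FALSE]
    }
    proj <- coords %*% directions                      # n x k_true
    proj_sd <- apply(proj, 2, stats::sd)
    if (is.null(loading_scale)) {
      loading_scale <- snr * max(noise_sd, 1e-12) / mean(proj_sd)
    }
    mask <- matrix(FALSE, n_genes, k_true)
    loadings <- matrix(0, n_genes, k_true)
    for (j in seq_len(k_true)) {
      n_grad <- max(1L, round(frac_gradient_genes[j] * n_genes))
      idx <- sample.int(n_genes, n_grad)
      mask[idx, j] <- TRUE
      loadings[idx, j] <- loading_scale *
        sample(c(-1, 1), n_grad, replace = TRUE) *
        stats::runif(n_grad, 0.5, 1.5)
    }
    signal <- proj %*% t(loadings)                     # n x n_genes
    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(n * n_genes, sd = noise_sd), n, n_genes)
    } else 0
    expr <- signal + noise
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    colnames(expr) <- gene_ids
    rownames(loadings) <- gene_ids
    rownames(mask) <- gene_ids
    ds <- expression_dataset(expr, coords = coords, species = "synthetic")
    truth <- structure(
      list(directions = directions, gene_loadings = loadings,
           gradient_gene_mask = mask, noise_sd = noise_sd,
           loading_scale = loading_scale,
           snr = loading_scale * proj_sd / max(noise_sd, 1e-12)),
      class = "synthetic_truth")
    list(dataset = ds, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", ncol(x$directions), "planted gradient(s),",
      "noise_sd", signif(x$noise_sd, 3), "\n")
  cat("  per-gradient SNR:", paste(signif(x$snr, 3), collapse = ", "), "\n")
  invisible(x)
}

# Regenerate noise-free expression from a truth object at given coordinates.
truth_signal <- function(truth, coords) {
  as.matrix(coords) %*% truth$directions %*% t(truth$gene_loadings)
}

#' Default regional sampling frame for replica generators
#'
#' Seeded random region centroids inside an ellipsoid, mimicking datasets
#' that sample a fixed panel of named brain regions.
#'
#' @param n_regions number of regions (>= 2).
#' @param semi_axes_mm ellipsoid semi-axes, mm.
#' @param seed RNG seed.
#' @return `n_regions x 3` matrix with region names as rownames.
#' @export
make_region_centroids <- function(n_regions = 16, semi_axes_mm = c(70, 85, 65),
                                  seed = 1) {
  stopifnot(n_regions >= 2)
  cent <- generate_brain_cloud(n_regions, semi_axes_mm * 0.8, seed = seed)
  rownames(cent) <- sprintf("region%02d", seq_len(n_regions))
  cent
}

#' Generate external replication datasets from a planted truth
#'
#' Each simulated individual samples tissue near a fixed panel of region
#' centroids, keeps a seeded random subset of the discovery genes, and
#' regenerates expression from the shared truth plus individual-level noise.
#' This emulates replication cohorts that measure different regions and gene
#' panels than the discovery atlas.
#'
#' @param truth `synthetic_truth` from [plant_gradients()].
#' @param region_centroids `n_regions x 3` matrix (>= 2 regions) with region
#'   names as rownames; see [make_region_centroids()].
#' @param genes_kept_frac fraction of discovery genes retained, in (0, 1].
#' @param samples_per_region tissue samples drawn per region.
#' @param indiv_noise_sd per-individual additive expression noise SD.
#' @param n_individuals number of simulated individuals.
#' @param sample_spread_mm SD of the isotropic scatter of samples around
#'   their region centroid.
#' @param species species tag attached to each dataset.
#' @param ages_pcw optional per-individual age (post-conception weeks).
#' @param seed RNG seed.
#' @return list of [expression_dataset()]s, one per individual.
#' @export
make_external_replica <- function(truth, region_centroids,
                                  genes_kept_frac = 1,
                                  samples_per_region = 4,
                                  indiv_noise_sd = truth$noise_sd,
                                  n_individuals = 1,
                                  sample_spread_mm = 3,
                                  species = "synthetic",
                                  ages_pcw = NULL, seed = 1) {
  region_centroids <- as.matrix(region_centroids)
  if (nrow(region_centroids) < 2) {
    stop("need >= 2 regions: regional correlation is undefined otherwise")
  }
  stopifnot(genes_kept_frac > 0, genes_kept_frac <= 1)
  n_genes <- nrow(truth$gene_loadings)
  gene_ids <- rownames(truth$gene_loadings)
  regions <- rownames(region_centroids) %||%
    sprintf("region%02d", seq_len(nrow(region_centroids)))
  with_seed(seed, {
    lapply(seq_len(n_individuals), function(i) {
      keep <- sort(sample.int(n_genes, max(1L, round(genes_kept_frac * n_genes))))
      n_r <- nrow(region_centroids)
      coords <- region_centroids[rep(seq_len(n_r), each = samples_per_region), ,
                                 drop = FALSE]
      if (sample_spread_mm > 0) {
        coords <- coords + matrix(stats::rnorm(length(coords),
                                               sd = sample_spread_mm),
                                  nrow(coords), 3)
      }
      rownames(coords) <- NULL
      expr <- truth_signal(truth, coords)[, keep, drop = FALSE]
      if (indiv_noise_sd > 0) {
        expr <- expr + matrix(stats::rnorm(length(expr), sd = indiv_noise_sd),
                              nrow(expr), ncol(expr))
      }
      dimnames(expr) <- list(NULL, gene_ids[keep])
      expression_dataset(
        expr, coords = coords,
        region = rep(regions, each = samples_per_region),
        donor = sprintf("indiv%02d", i),
        age_pcw = if (!is.null(ages_pcw)) ages_pcw[i],
        species = species)
    })
  })
}

#' Logistic developmental fidelity curve
#'
#' Returns a monotone non-decreasing function of age (post-conception weeks)
#' with values in `[floor, 1)`:
#' `f(a) = floor + (1 - floor) / (1 + exp(-slope * (log(a) - log(midpoint))))`.
#' Age enters on the log scale, matching how developmental trajectories are
#' usually plotted.
#'
#' @param floor lower asymptote in `[0, 1]` (fidelity already present at the
#'   earliest ages).
#' @param slope logistic steepness (>= 0) on the log-age scale.
#' @param midpoint_pcw age (pcw) at the half-rise point.
#' @return function mapping age_pcw to fidelity in `[0, 1]`.
#' @export
fidelity_curve <- function(floor = 0, slope = 3, midpoint_pcw = 40) {
  stopifnot(floor >= 0, floor <= 1, slope >= 0, midpoint_pcw > 0)
  force(floor); force(slope); force(midpoint_pcw)
  function(age_pcw) {
    stopifnot(all(age_pcw > 0))
    floor + (1 - floor) / (1 + exp(-slope * (log(age_pcw) - log(midpoint_pcw))))
  }
}

#' Default developmental epoch boundaries (post-conception weeks)
#'
#' Prenatal < 40 pcw; postnatal 40-976 pcw (birth to ~18 years);
#' adult > 976 pcw. Declared package defaults, configurable wherever used.
#' @export
default_epochs <- function() c(prenatal = 0, postnatal = 40, adult = 976, end = Inf)

#' Plan epoch-limited activity for gradient genes
#'
#' Assigns each gradient gene one developmental epoch during which its
#' loading is active; outside that window the gene contributes noise only.
#' A seeded fraction of gradient genes is flagged nontransitional and stays
#' active (with the adult pattern) at all ages.
#'
#' @param truth `synthetic_truth`.
#' @param epochs named breakpoints as in [default_epochs()].
#' @param frac_nontransitional fraction of gradient genes active at all ages.
#' @param seed RNG seed.
#' @return list with `epoch` (factor per gene, NA for non-gradient genes),
#'   `nontransitional` (logical per gene), `epochs`.
#' @export
make_epoch_gene_plan <- function(truth, epochs = default_epochs(),
                                 frac_nontransitional = 0.1, seed = 1) {
  n_genes <- nrow(truth$gene_loadings)
  is_grad <- rowSums(truth$gradient_gene_mask) > 0
  epoch_names <- names(epochs)[seq_len(length(epochs) - 1L)]
  with_seed(seed, {
    epoch <- rep(NA_character_, n_genes)
    epoch[is_grad] <- sample(epoch_names, sum(is_grad), replace = TRUE)
    nontrans <- rep(FALSE, n_genes)
    grad_idx <- which(is_grad)
    n_nt <- round(frac_nontransitional * length(grad_idx))
    if (n_nt > 0) nontrans[sample(grad_idx, n_nt)] <- TRUE
    list(epoch = factor(epoch, levels = epoch_names),
         nontransitional = nontrans, epochs = epochs)
  })
}

# Epoch label of an age under a breakpoint vector.
age_epoch <- function(age_pcw, epochs = default_epochs()) {
  names(epochs)[findInterval(age_pcw, epochs)]
}

#' Generate a developmental series of regional datasets
#'
#' One individual per age. At age `a`, gradient `j`'s genes express a mixture
#' of the adult gradient and a spatially incoherent "immature" regional
#' pattern: the adult component is weighted by `fidelity_j(a)` and the
#' immature component by `1 - fidelity_j(a)`, plus noise. The immature
#' pattern is a fixed seeded random value per (region, gradient), so low
#' fidelity produces regional expression that is reproducible but
#' uncorrelated with the adult gradient; similarity to the adult gradient is
#' then a strictly increasing function of fidelity even without noise.
#'
#' Under an `epoch_gene_plan`, a gradient gene carries the adult pattern only
#' within its active epoch (contributing its immature/noise components
#' otherwise), while nontransitional genes carry the full adult pattern at
#' every age.
#'
#' @param truth `synthetic_truth`.
#' @param region_centroids `n_regions x 3` matrix of sampled regions.
#' @param fidelity_curves list of `k_true` functions age -> fidelity in
#'   `[0,1]` (see [fidelity_curve()]).
#' @param ages_pcw ascending positive ages, one individual per age.
#' @param epoch_gene_plan optional plan from [make_epoch_gene_plan()].
#' @param samples_per_region samples per region per individual.
#' @param noise_sd additive expression noise SD (0 for noise-free fixtures).
#' @param sample_spread_mm scatter of samples around centroids, mm.
#' @param species species tag.
#' @param seed RNG seed.
#' @return list of [expression_dataset()]s with `age_pcw` set.
#' @export
make_developmental_series <- function(truth, region_centroids, fidelity_curves,
                                      ages_pcw, epoch_gene_plan = NULL,
                                      samples_per_region = 4, noise_sd = 0.5,
                                      sample_spread_mm = 0,
                                      species = "synthetic", seed = 1) {
  if (length(ages_pcw) == 0) stop("ages_pcw must be non-empty")
  if (is.unsorted(ages_pcw)) stop("ages_pcw must be sorted ascending")
  stopifnot(all(ages_pcw > 0))
  k_true <- ncol(truth$directions)
  if (length(fidelity_curves) != k_true) {
    stop("need one fidelity curve per planted gradient")
  }
  region_centroids <- as.matrix(region_centroids)
  n_r <- nrow(region_centroids)
  regions <- rownames(region_centroids) %||% sprintf("region%02d", seq_len(n_r))
  gene_ids <- rownames(truth$gene_loadings)
  with_seed(seed, {
    # Fixed immature regional pattern per (region, gradient).
    immature <- matrix(stats::rnorm(n_r * k_true), n_r, k_true)
    immature <- sweep(immature, 2, apply(region_centroids %*% truth$directions,
                                         2, stats::sd), "*")
    lapply(seq_along(ages_pcw), function(i) {
      a <- ages_pcw[i]
      fid <- vapply(fidelity_curves, function(f) f(a), numeric(1))
      coords <- region_centroids[rep(seq_len(n_r), each = samples_per_region), ,
                                 drop = FALSE]
      rownames(coords) <- NULL
      if (sample_spread_mm > 0) {
        coords <- coords + matrix(stats::rnorm(length(coords),
                                               sd = sample_spread_mm),
                                  nrow(coords), 3)
      }
      reg_idx <- rep(seq_len(n_r), each = samples_per_region)
      adult_proj <- coords %*% truth$directions         # n x k
      imm_proj <- immature[reg_idx, , drop = FALSE]     # n x k
      # Per-gene activity: adult-pattern weight per (gene, gradient).
      adult_w <- matrix(rep(fid, each = nrow(truth$gene_loadings)),
                        nrow(truth$gene_loadings), k_true)
      imm_w <- 1 - adult_w
      if (!is.null(epoch_gene_plan)) {
        ep <- age_epoch(a, epoch_gene_plan$epochs)
        inactive <- !is.na(epoch_gene_plan$epoch) &
          epoch_gene_plan$epoch != ep & !epoch_gene_plan$nontransitional
        adult_w[inactive, ] <- 0        # outside the window: noise only
        imm_w[inactive, ] <- 0
        adult_w[epoch_gene_plan$nontransitional, ] <- 1
        imm_w[epoch_gene_plan$nontransitional, ] <- 0
      }
      load_adult <- truth$gene_loadings * adult_w
      load_imm <- truth$gene_loadings * imm_w
      expr <- adult_proj %*% t(load_adult) + imm_proj %*% t(load_imm)
      if (noise_sd > 0) {
        expr <- expr + matrix(stats::rnorm(length(expr), sd = noise_sd),
                              nrow(expr), ncol(expr))
      }
      colnames(expr) <- gene_ids
      expression_dataset(
        expr, coords = coords,
        region = regions[reg_idx],
        donor = sprintf("dev%02d", i), age_pcw = a, species = species)
    })
  })
}

# ---- surface fixtures --------------------------------------------------------

# Unit icosahedron mesh.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"
  list(vertices = v, faces = f)
}

# One loop subdivision step on a sphere mesh (midpoints re-projected).
subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midcache <- new.env(hash = TRUE, parent = emptyenv())
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j), sep = "_")
    got <- get0(key, envir = midcache)
    if (!is.null(got)) return(got)
    m <- (verts[[i]] + verts[[j]]) / 2
    m <- m / sqrt(sum(m^2))
    verts[[length(verts) + 1L]] <<- m
    idx <- length(verts)
    assign(key, idx, envir = midcache)
    idx
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts), faces = newf)
}

#' Build an icosphere with at least `n_vertices` vertices
#'
#' @param n_vertices minimum vertex count (possible counts: 12, 42, 162,
#'   642, 2562, ...).
#' @return list with unit `vertices` and integer `faces`.
#' @export
icosphere <- function(n_vertices = 42) {
  mesh <- icosahedron()
  while (nrow(mesh$vertices) < n_vertices) mesh <- subdivide_sphere(mesh)
  mesh
}

# Vertex adjacency-mean sparse operator from faces.
adjacency_operator <- function(faces, n_vertices) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  a <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(n_vertices, n_vertices))
  deg <- Matrix::rowSums(a)
  Matrix::Diagonal(x = 1 / pmax(deg, 1)) %*% a
}

#' Generate a cortical surface fixture with smooth random maps
#'
#' Builds an icosphere (sphere mesh), scales it anisotropically into an
#' "anatomical" mesh, and draws `n_maps` spatially smooth random fields by
#' iterated neighborhood averaging of white noise (each iteration replaces a
#' vertex value by the mean of itself and its neighbor average). Maps are
#' z-scored. Deterministic given the seed.
#'
#' @param n_vertices minimum vertex count (>= 42).
#' @param smooth_iter number of neighborhood-averaging iterations (0 gives
#'   white noise; ~10-40 gives smooth fields at icosphere resolutions).
#' @param n_maps number of independent maps.
#' @param semi_axes_mm anatomical scaling of the sphere, mm.
#' @param mask_frac fraction of vertices flagged as medial wall (a contiguous
#'   polar cap), default 0.
#' @param seed RNG seed.
#' @return list with `surface` (a [surface_pair()]) and `maps`
#'   (`n_vertices x n_maps` matrix, `NA` at masked vertices).
#' @export
make_surface_fixture <- function(n_vertices = 642, smooth_iter = 20,
                                 n_maps = 1, semi_axes_mm = c(70, 85, 65),
                                 mask_frac = 0, seed = 1) {
  stopifnot(n_vertices >= 42, smooth_iter >= 0, n_maps >= 1)
  mesh <- icosphere(n_vertices)
  nv <- nrow(mesh$vertices)
  anat <- sweep(mesh$vertices, 2, semi_axes_mm, "*")
  mask <- rep(FALSE, nv)
  if (mask_frac > 0) {
    ord <- order(mesh$vertices[, 3])          # inferior polar cap
    mask[ord[seq_len(round(mask_frac * nv))]] <- TRUE
  }
  surf <- surface_pair(anat, mesh$vertices, mesh$faces, medial_mask = mask)
  op <- adjacency_operator(mesh$faces, nv)
  maps <- with_seed(seed, {
    m <- matrix(stats::rnorm(nv * n_maps), nv, n_maps)
    for (it in seq_len(smooth_iter)) {
      m <- 0.5 * m + 0.5 * as.matrix(op %*% m)
    }
    scale(m)
  })
  maps <- matrix(as.numeric(maps), nv, n_maps)
  maps[mask, ] <- NA_real_
  colnames(maps) <- sprintf("map%02d", seq_len(n_maps))
  list(surface = surf, maps = maps)
}
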