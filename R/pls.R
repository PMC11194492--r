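#' Fit a PLS regression of spatial coordinates on gene expression
#'
#' Cross-decomposes the per-gene z-scored expression matrix X with the
#' centered (not scaled) coordinate matrix Y by sequential PLS2 extraction
#' with X-deflation only. For each component j, the x-weight `w_j` is the
#' leading left singular vector of `t(X_j) %*% Y` (X_j the j-times-deflated
#' X), `t_j = X_j w_j` is the latent transcriptomic variable, and
#' `u_j = Y c_j / ||c_j||` the latent spatial variable. Coordinates stay in
#' mm so prediction errors are interpretable in mm.
#'
#' Each component's sign is anchored so that the coordinate axis with the
#' largest |y-loading| has a positive loading (ties broken in x < y < z
#' order); replication correlations elsewhere in the package are reported on
#' anchor-aligned scores.
#'
#' Zero-variance genes are dropped with a warning before fitting. If fewer
#' than `k` non-degenerate components are extractable the fit errors.
#'
#' @param dataset an [expression_dataset()] with coordinates.
#' @param k number of components (1-3).
#' @param strict error when fewer than `k` non-degenerate components are
#'   extractable (default). With `strict = FALSE` extraction stops early and
#'   the returned model has the extractable `k` (used by cross-validation on
#'   possibly rank-deficient folds).
#' @return object of class `pls_model` with elements `gene_mean`, `gene_sd`,
#'   `coord_mean`, x-weights `W` (unit-norm columns), x-loadings `P`,
#'   y-loadings `C`, regression coefficients `B = W (P'W)^-1 C'`, training
#'   scores `T` (transcriptomic) and `U` (spatial), `k`, `gene_ids`,
#'   `sign_anchor`, `train_ids`.
#' @export
fit_pls <- function(dataset, k = 3, strict = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$coords)) stop("dataset has no coordinates; cannot fit")
  k <- as.integer(k)
  if (k < 1L || k > 3L) stop("k must be between 1 and 3")
  n <- nrow(dataset$expression)
  if (n <= k) stop("need more samples than components")

  x_raw <- dataset$expression
  gene_sd_all <- apply(x_raw, 2, stats::sd)
  keep <- gene_sd_all > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance gene(s) before fit")
    x_raw <- x_raw[, keep, drop = FALSE]
  }
  gene_ids <- colnames(x_raw)
  gene_mean <- colMeans(x_raw)
  gene_sd <- gene_sd_all[keep]
  x <- sweep(sweep(x_raw, 2, gene_mean, "-"), 2, gene_sd, "/")
  coord_mean <- colMeans(dataset$coords)
  y <- sweep(dataset$coords, 2, coord_mean, "-")

  g <- ncol(x)
  W <- matrix(0, g, k); P <- matrix(0, g, k)
  C <- matrix(0, 3L, k)
  TT <- matrix(0, n, k); U <- matrix(0, n, k)
  anchor <- integer(k)
  xj <- x
  sv1 <- NA_real_
  for (j in seq_len(k)) {
    m <- crossprod(xj, y)                       # g x 3 cross-covariance
    s <- crossprod(m)                           # 3 x 3 Gram matrix
    eg <- eigen(s, symmetric = TRUE)
    q <- eg$vectors[, 1]
    mv <- m %*% q
    nm <- sqrt(sum(mv^2))
    if (j == 1L) sv1 <- nm
    if (nm < 1e-10 * max(sv1, .Machine$double.eps)) {
      if (strict) {
        stop("fewer than ", k, " non-degenerate components extractable ",
             "(component ", j, " has vanishing cross-covariance)")
      }
      k <- j - 1L
      if (k == 0L) stop("no non-degenerate component extractable")
      W <- W[, seq_len(k), drop = FALSE]; P <- P[, seq_len(k), drop = FALSE]
      C <- C[, seq_len(k), drop = FALSE]
      TT <- TT[, seq_len(k), drop = FALSE]; U <- U[, seq_len(k), drop = FALSE]
      anchor <- anchor[seq_len(k)]
      break
    }
    w <- as.vector(mv) / nm
    t_ <- as.vector(xj %*% w)
    tt <- sum(t_^2)
    p <- as.vector(crossprod(xj, t_)) / tt
    cc <- as.vector(crossprod(y, t_)) / tt
    u <- as.vector(y %*% cc) / sqrt(sum(cc^2))
    a <- which.max(abs(cc))                     # sign anchor: dominant axis
    if (cc[a] < 0) {
      w <- -w; t_ <- -t_; p <- -p; cc <- -cc; u <- -u
    }
    W[, j] <- w; P[, j] <- p; C[, j] <- cc
    TT[, j] <- t_; U[, j] <- u
    anchor[j] <- a
    xj <- xj - tcrossprod(t_, p)
  }
  B <- W %*% solve(crossprod(P, W), t(C))
  rownames(W) <- rownames(P) <- rownames(B) <- gene_ids
  colnames(W) <- colnames(P) <- colnames(C) <- paste0("LV", seq_len(k))
  colnames(TT) <- colnames(U) <- paste0("LV", seq_len(k))
  colnames(B) <- c("x", "y", "z")
  rownames(TT) <- rownames(U) <- dataset$sample_ids
  structure(list(gene_mean = gene_mean, gene_sd = gene_sd,
                 coord_mean = coord_mean, W = W, P = P, C = C, B = B,
                 T = TT, U = U, k = k, gene_ids = gene_ids,
                 sign_anchor = anchor, train_ids = dataset$sample_ids),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", x$k, "components,", length(x$gene_ids), "genes,",
      nrow(x$T), "training samples\n")
  r <- latent_correlations(x)
  cat("  latent spatial-transcriptomic correlations:",
      paste(signif(r, 3), collapse = ", "), "\n")
  invisible(x)
}

# Standardize a dataset's expression with the model's training statistics,
# in the model's gene order. Errors if model genes are missing.
standardize_for_model <- function(model, dataset) {
  miss <- setdiff(model$gene_ids, dataset$gene_ids)
  if (length(miss)) {
    stop(length(miss), " model gene(s) missing from dataset ",
         "(refit_on_shared_genes first); first missing: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  x <- dataset$expression[, model$gene_ids, drop = FALSE]
  sweep(sweep(x, 2, model$gene_mean, "-"), 2, model$gene_sd, "/")
}

#' Project a dataset onto fitted gradient components
#'
#' Computes latent transcriptomic scores for new samples by standardizing
#' expression with the model's training statistics and replaying the
#' deflation with the stored weights and x-loadings. On the training data
#' this reproduces the stored scores `T`.
#'
#' @param model a fitted `pls_model`.
#' @param dataset an [expression_dataset()] whose genes are a superset of the
#'   model's genes.
#' @return a [gradient_scores()] at sample level.
#' @export
transform_scores <- function(model, dataset) {
  stopifnot(inherits(model, "pls_model"))
  x <- standardize_for_model(model, dataset)
  n <- nrow(x)
  scores <- matrix(0, n, model$k)
  for (j in seq_len(model$k)) {
    t_ <- as.vector(x %*% model$W[, j])
    scores[, j] <- t_
    x <- x - tcrossprod(t_, model$P[, j])
  }
  gradient_scores(dataset$sample_ids, scores, level = "sample")
}

#' Predict sample coordinates from gene expression
#'
#' @param model a fitted `pls_model`.
#' @param dataset an [expression_dataset()] covering the model's genes.
#' @return numeric `n x 3` matrix of predicted mm coordinates.
#' @export
predict_coordinates <- function(model, dataset) {
  x <- standardize_for_model(model, dataset)
  pred <- x %*% model$B
  pred <- sweep(pred, 2, model$coord_mean, "+")
  rownames(pred) <- dataset$sample_ids
  colnames(pred) <- c("x", "y", "z")
  pred
}

#' Per-axis coefficient of determination of coordinate predictions
#'
#' `R^2 = 1 - SSE/SST` per axis; can be negative for models worse than the
#' mean. A zero-variance axis yields `NA` with a warning.
#'
#' @param true_coords,predicted numeric `n x 3` matrices.
#' @return length-3 numeric vector named x, y, z.
#' @export
coordinate_r2 <- function(true_coords, predicted) {
  true_coords <- as.matrix(true_coords); predicted <- as.matrix(predicted)
  stopifnot(all(dim(true_coords) == dim(predicted)))
  out <- vapply(seq_len(ncol(true_coords)), function(a) {
    sst <- sum((true_coords[, a] - mean(true_coords[, a]))^2)
    if (sst == 0) {
      warning("axis ", a, " has zero variance; R^2 undefined")
      return(NA_real_)
    }
    1 - sum((true_coords[, a] - predicted[, a])^2) / sst
  }, numeric(1))
  names(out) <- c("x", "y", "z")[seq_along(out)]
  out
}

#' Mean Euclidean coordinate prediction error
#'
#' @param true_coords,predicted numeric `n x 3` matrices in mm.
#' @return list with `mean` (mm) and `per_sample` distance vector for
#'   error-topography plots.
#' @export
mean_prediction_error <- function(true_coords, predicted) {
  true_coords <- as.matrix(true_coords); predicted <- as.matrix(predicted)
  stopifnot(all(dim(true_coords) == dim(predicted)))
  d <- sqrt(rowSums((true_coords - predicted)^2))
  list(mean = mean(d), per_sample = d)
}

#' Correlations between latent spatial and transcriptomic variables
#'
#' Pearson correlation between each pair of training score columns
#' (`T[,j]`, `U[,j]`), reported as fitted under the anchor sign convention
#' (not forced positive). Degenerate score variance yields `NA`.
#'
#' @param model a fitted `pls_model` with stored training scores.
#' @return numeric vector of length `k`.
#' @export
latent_correlations <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  vapply(seq_len(model$k), function(j) {
    if (stats::sd(model$T[, j]) == 0 || stats::sd(model$U[, j]) == 0) {
      return(NA_real_)
    }
    stats::cor(model$T[, j], model$U[, j])
  }, numeric(1))
}

# Coefficients truncated to the first k components of a fitted model
# (used by cross-validation to score nested models from one fit).
coef_for_k <- function(model, k) {
  w <- model$W[, seq_len(k), drop = FALSE]
  p <- model$P[, seq_len(k), drop = FALSE]
  cc <- model$C[, seq_len(k), drop = FALSE]
  w %*% solve(crossprod(p, w), t(cc))
}
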