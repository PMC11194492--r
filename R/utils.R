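# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# All permutations of 1:n as an n!-row matrix (n <= 8 in practice).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

# Optimal pairing of reference components (rows of `r_mat`) with candidate
# components (columns) maximizing the total |correlation|.  k <= 3 here, so
# exhaustive enumeration over permutations is exact assignment.
pair_components <- function(r_mat) {
  k <- nrow(r_mat)
  stopifnot(ncol(r_mat) == k)
  perms <- all_perms(k)
  best <- -Inf
  best_p <- seq_len(k)
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    s <- sum(abs(r_mat[cbind(seq_len(k), p)]))
    if (s > best) {
      best <- s
      best_p <- p
    }
  }
  r_sel <- r_mat[cbind(seq_len(k), best_p)]
  list(order = best_p, signs = ifelse(r_sel >= 0, 1, -1),
       abs_r = abs(r_sel))
}

# Uniform random rotation matrix (Haar measure), determinant +1.
random_rotation <- function() {
  a <- matrix(stats::rnorm(9), 3L, 3L)
  qrd <- qr(a)
  q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Add-one permutation p-value.
perm_pvalue <- function(n_exceed, n_perm) (1 + n_exceed) / (n_perm + 1)

# Detect the delimiter of a delimited text file (tab vs comma).
detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) >=
      lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a
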