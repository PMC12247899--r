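#' Generate a seeded Gaussian random-projection matrix
#'
#' Entries are drawn i.i.d. from \eqn{N(0, 1/k)}, the scaling under which the
#' projection \eqn{y = x R} preserves Euclidean norms in expectation and
#' pairwise distances with high probability (Johnson-Lindenstrauss). The
#' matrix is a pure function of `(d, k, seed)`: regeneration is bit-identical,
#' which is what lets fitted pipelines store seeds instead of matrices.
#'
#' @param d input dimensionality (genes), `>= 1`.
#' @param k target dimensionality, `>= 1` (typically `k << d`).
#' @param seed RNG seed.
#' @return object of class `projection_matrix`: list with `entries` (`d x k`),
#'   `d`, `k`, `seed`.
#' @export
generate_projection <- function(d, k, seed) {
  d <- check_count(d, "d")
  k <- check_count(k, "k")
  entries <- withr::with_seed(seed, matrix(rnorm(d * k, mean = 0, sd = 1 / sqrt(k)), d, k))
  structure(list(entries = entries, d = d, k = k, seed = as.integer(seed)),
            class = "projection_matrix")
}

#' Project samples through a random-projection matrix
#'
#' Computes the exact matrix product `X %*% R`; each output row depends only
#' on the corresponding input row.
#'
#' @param X `n x d` numeric matrix (or an [expr_dataset()], whose values are
#'   used).
#' @param R a [generate_projection()] result.
#' @return `n x k` numeric matrix.
#' @export
project <- function(X, R) {
  if (inherits(X, "expr_dataset")) X <- X$values
  if (!inherits(R, "projection_matrix")) abort("'R' must be a projection_matrix")
  if (ncol(X) != R$d)
    abort(sprintf("dimension mismatch: X is %d x %d but R is %d x %d",
                  nrow(X), ncol(X), R$d, R$k))
  X %*% R$entries
}

#' Fuse multiple independent random projections
#'
#' Derives `m` child seeds from `master_seed` by the counter scheme of
#' [derive_child_seeds()], generates `m` independent projection matrices,
#' projects, and concatenates column-wise in seed order. Block `j` of the
#' output (columns `(j-1)*k + 1 .. j*k`) is reproducible in isolation from
#' its recorded child seed. Blocks are not re-scaled after concatenation;
#' each already carries the `1/k` variance scaling.
#'
#' @param X `n x d` matrix or [expr_dataset()].
#' @param k per-projection dimension.
#' @param m number of independent projections, `>= 1`.
#' @param master_seed seed from which the `m` child seeds are derived.
#' @return object of class `fused_features`: list with `values`
#'   (`n x (m*k)`), `k`, `m`, `seeds` (the child seeds, concatenation order).
#' @export
fuse_projections <- function(X, k, m, master_seed) {
  if (inherits(X, "expr_dataset")) X <- X$values
  k <- check_count(k, "k")
  m <- check_count(m, "m")
  seeds <- derive_child_seeds(master_seed, m)
  d <- ncol(X)
  out <- matrix(0, nrow(X), m * k)
  for (j in seq_len(m)) {
    R <- generate_projection(d, k, seeds[j])
    out[, ((j - 1) * k + 1):(j * k)] <- X %*% R$entries
  }
  rownames(out) <- rownames(X)
  structure(list(values = out, k = k, m = m, seeds = seeds),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf("<fused_features> %d x %d (m = %d blocks of k = %d)\n",
              nrow(x$values), ncol(x$values), x$m, x$k))
  invisible(x)
}

#' Pearson correlation of pairwise distances before and after reduction
#'
#' The distance-preservation diagnostic: all `n(n-1)/2` pairwise Euclidean
#' distances are computed in the original and the reduced space and their
#' Pearson correlation is returned. Any externally produced embedding (PCA,
#' t-SNE, UMAP coordinates) can be scored by passing it as `X_reduced`.
#'
#' @param X_original `n x d` matrix or [expr_dataset()].
#' @param X_reduced `n x k'` matrix, [fused_features()] or [expr_dataset()]
#'   over the same `n` samples in the same order.
#' @return correlation in `[-1, 1]`.
#' @export
distance_preservation <- function(X_original, X_reduced) {
  if (inherits(X_original, "expr_dataset")) X_original <- X_original$values
  if (inherits(X_reduced, "expr_dataset")) X_reduced <- X_reduced$values
  if (inherits(X_reduced, "fused_features")) X_reduced <- X_reduced$values
  if (nrow(X_original) != nrow(X_reduced))
    abort("matrices must cover the same samples: ",
          nrow(X_original), " vs ", nrow(X_reduced), " rows")
  if (nrow(X_original) < 3) abort("need at least 3 samples for a distance correlation")
  d0 <- as.vector(dist(X_original))
  d1 <- as.vector(dist(X_reduced))
  if (sd(d0) == 0 || sd(d1) == 0)
    abort("zero-variance distance vector; correlation undefined")
  cor(d0, d1)
}
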