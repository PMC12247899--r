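#' Specification of a synthetic two-subtype bulk RNA-seq cohort
#'
#' Describes a seeded generative model for a TPM-scale expression matrix with
#' two balanced sample classes, a planted minority of differentially expressed
#' (DE) genes, and block-correlated co-expression structure. Expression is
#' log-normal: gene values are `2^x` where `x` follows a Gaussian
#' log2-expression model, matching the multiplicative character of expression
#' data and the `log2(TPM + 1)` transform used downstream.
#'
#' @param n_per_class samples per subtype (positive integer).
#' @param d number of genes.
#' @param n_de number of DE genes (`n_de <= d`); half shifted up in the first
#'   class, half down, so the volcano of class differences is two-sided.
#' @param lfc mean absolute log2 fold-change planted on DE genes: class means
#'   differ by `lfc` on the log2 scale (shift of `lfc/2` either side).
#' @param block_size genes per correlated block; consecutive genes share a
#'   latent factor per sample.
#' @param rho within-block pairwise Pearson correlation of log-expression,
#'   in `[0, 1)`; achieved exactly in expectation via the shared factor.
#' @param noise_sd per-gene log2-scale standard deviation (> 0).
#' @param seed RNG seed; identical specs reproduce byte-identical datasets.
#' @return an object of class `synthetic_spec`.
#' @seealso [generate_dataset()]
#' @export
synthetic_spec <- function(n_per_class = 100, d = 5000, n_de = 250, lfc = 1,
                           block_size = 50, rho = 0.4, noise_sd = 1, seed = 1) {
  n_per_class <- check_count(n_per_class, "n_per_class")
  d <- check_count(d, "d")
  block_size <- check_count(block_size, "block_size")
  if (!is.numeric(n_de) || n_de < 0 || n_de != round(n_de))
    abort("'n_de' must be a nonnegative integer")
  if (n_de > d) abort(sprintf("'n_de' (%d) exceeds 'd' (%d)", as.integer(n_de), d))
  if (!is.numeric(lfc) || lfc < 0) abort("'lfc' must be nonnegative")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) abort("'rho' must be in [0, 1)")
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("'noise_sd' must be > 0")
  if (!is.numeric(seed) || seed != round(seed)) abort("'seed' must be an integer")
  structure(list(n_per_class = n_per_class, d = d, n_de = as.integer(n_de),
                 lfc = lfc, block_size = block_size, rho = rho,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-subtype expression dataset
#'
#' Draws a `2 * n_per_class` by `d` TPM-scale matrix under the log-normal
#' model of [synthetic_spec()]: per-gene baseline log2 means ~ N(3, 2) (TPM
#' values spanning roughly 1e-1 to 1e3), block covariance through one shared
#' latent factor per block (`x = mu + delta + noise_sd * (sqrt(rho) z_block +
#' sqrt(1-rho) eps)`), and a class-mean shift of `+/- lfc/2` on the `n_de`
#' designated DE genes. Labels are balanced `LUAD` / `LUSC`. The planted
#' truth (DE gene indices and directions) is attached as attribute `"truth"`.
#'
#' @param spec a [synthetic_spec()].
#' @return an [expr_dataset()] with `scale = "tpm"`, plus attribute `truth`:
#'   a list with `de_genes` (integer indices), `de_sign` (+1 = up in the
#'   first class), and the generating `spec`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("'spec' must be a synthetic_spec")
  n <- 2L * spec$n_per_class
  d <- spec$d
  labels <- factor(rep(c("LUAD", "LUSC"), each = spec$n_per_class))
  block <- ((seq_len(d) - 1L) %/% spec$block_size) + 1L
  n_block <- max(block)

  withr::with_seed(spec$seed, {
    mu <- rnorm(d, mean = 3, sd = 2)
    de_genes <- if (spec$n_de > 0) sort(sample.int(d, spec$n_de)) else integer(0)
    de_sign <- rep_len(c(1, -1), spec$n_de)  # half up, half down in class 1
    delta <- numeric(d)
    delta[de_genes] <- de_sign * spec$lfc / 2
    z <- matrix(rnorm(n * n_block), n, n_block)          # shared block factors
    eps <- matrix(rnorm(n * d), n, d)
    class_sign <- ifelse(labels == levels(labels)[1], 1, -1)
    logx <- spec$noise_sd * (sqrt(spec$rho) * z[, block, drop = FALSE] +
                               sqrt(1 - spec$rho) * eps)
    logx <- sweep(logx, 2, mu, `+`) + outer(class_sign, delta)
  })

  values <- 2^logx
  rownames(values) <- sprintf("S%04d", seq_len(n))
  colnames(values) <- sprintf("G%05d", seq_len(d))
  ds <- expr_dataset(values, labels = labels, scale = "tpm")
  attr(ds, "truth") <- list(de_genes = de_genes, de_sign = de_sign, spec = spec)
  ds
}
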