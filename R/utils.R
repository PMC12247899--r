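
`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

#' Derive reproducible child seeds from a master seed
#'
#' Counter-based derivation: child \eqn{j} is a fixed affine hash of the
#' master seed and the counter, reduced modulo \eqn{2^{31}-1}. Each child is
#' therefore reproducible in isolation from `(master_seed, j)` alone, and
#' child streams for different counters are unrelated.
#'
#' @param master_seed integer master seed.
#' @param m number of child seeds.
#' @return integer vector of length `m`, each in `[1, 2^31 - 2]`.
#' @export
derive_child_seeds <- function(master_seed, m) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1, m >= 1)
  p <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- as.numeric(master_seed) %% p
  # 69069 * s < 2^48 and 10007 * m tiny, so the doubles below are exact
  as.integer((s * 69069 + seq_len(m) * 10007) %% (p - 1) + 1)
}

#' Deterministic stratified K-fold assignment
#'
#' Depends only on the label vector (order included), `K` and `seed`; every
#' class is spread as evenly as possible across folds.
#'
#' @param labels class labels.
#' @param K number of folds; every class needs at least `K` members.
#' @param seed assignment seed.
#' @return integer fold id in `1..K` per sample.
#' @export
stratified_folds <- function(labels, K, seed) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < K)) {
    bad <- names(tab)[tab < K]
    abort(sprintf("class '%s' has %d member(s), fewer than %d folds",
                  bad[1], tab[bad[1]], K))
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[sample(idx)] <- rep_len(seq_len(K), length(idx))
    }
  })
  fold
}

# Numeric formatting that survives a write/read round trip exactly.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) sprintf("%.0f", v) else sprintf("%.17g", v)
  }, character(1))
  out
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x))
    abort(sprintf("'%s' must be a positive integer (got %s)", name,
                  paste(format(x), collapse = ",")))
  as.integer(x)
}
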