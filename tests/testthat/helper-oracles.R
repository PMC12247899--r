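# Independent brute-force oracles, kept free of the implementation paths
# they check.

# confusion-matrix metrics by explicit counting; AUC by pairwise comparison
# of every (positive, negative) pair with ties counted half
oracle_metrics <- function(y_true, y_pred, y_prob, positive) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    t_pos <- y_true[i] == positive
    p_pos <- y_pred[i] == positive
    if (t_pos && p_pos) tp <- tp + 1
    if (!t_pos && !p_pos) tn <- tn + 1
    if (!t_pos && p_pos) fp <- fp + 1
    if (t_pos && !p_pos) fn <- fn + 1
  }
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp == 0) NA else tp / (tp + fp)
  rec <- if (tp + fn == 0) NA else tp / (tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0
        else 2 * prec * rec / (prec + rec)
  if (tp == 0) f1 <- 0  # harmonic mean with zero numerator
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  pos <- which(y_true == positive)
  neg <- which(y_true != positive)
  auc <- NA_real_
  if (length(pos) && length(neg)) {
    s <- 0
    for (i in pos) for (j in neg) {
      if (y_prob[i] > y_prob[j]) s <- s + 1
      else if (y_prob[i] == y_prob[j]) s <- s + 0.5
    }
    auc <- s / (length(pos) * length(neg))
  }
  c(accuracy = acc, f1 = f1, mcc = mcc, auc = auc)
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  W_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
  p
}

# direct TPM arithmetic
oracle_tpm <- function(counts, lengths) {
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}
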