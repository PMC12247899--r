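#' Binary classification metrics
#'
#' Computes accuracy, positive-class F1, Matthews correlation coefficient and
#' AUC. MCC returns 0 when any factor of its denominator is 0. AUC uses the
#' rank-statistic (Mann-Whitney) formulation with midranks for ties, and is
#' therefore invariant to strictly monotone transforms of the scores. With a
#' single-class truth vector AUC is undefined: it is returned as `NA` with
#' attribute `auc_undefined = TRUE`.
#'
#' @param y_true,y_pred binary label vectors (factor or character).
#' @param y_prob_positive score aligned to the `positive` class.
#' @param positive the positive class; defaults to the lexicographically
#'   larger label (so `"LUSC"` for LUAD/LUSC).
#' @return named numeric vector `(accuracy, f1, mcc, auc)`.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob_positive = NULL,
                            positive = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  classes <- sort(unique(c(y_true, y_pred)))
  if (length(classes) > 2) abort("compute_metrics is binary only")
  positive <- positive %||% classes[length(classes)]
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  acc <- (tp + tn) / length(y_true)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  auc <- NA_real_
  flag <- FALSE
  if (!is.null(y_prob_positive)) {
    pos <- y_true == positive
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      flag <- TRUE
    } else {
      r <- rank(y_prob_positive)  # midranks
      auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  out <- c(accuracy = acc, f1 = f1, mcc = mcc, auc = auc)
  if (flag) attr(out, "auc_undefined") <- TRUE
  out
}

#' Wrap a model type as a cross-validation estimator
#'
#' An estimator is a named pair of functions `fit(train_ds)` and
#' `predict(model, test_ds)` returning the standard prediction data.frame.
#' Constructors are provided for the stacked pipeline, the score-ensemble
#' baseline, any single base learner on the fused features, and the
#' ANOVA-selection comparators.
#'
#' @param config a [rpslearner_config()].
#' @return an `rpstack_estimator` list.
#' @export
estimator_rpslearner <- function(config = rpslearner_config()) {
  structure(list(name = "rpslearner",
                 fit = function(tr) fit_rpslearner(tr, config),
                 predict = function(m, te) predict(m, te)),
            class = "rpstack_estimator")
}

#' @rdname estimator_rpslearner
#' @export
estimator_score_ensemble <- function(config = rpslearner_config()) {
  structure(list(name = "score_ensemble",
                 fit = function(tr) fit_score_ensemble(tr, config),
                 predict = function(m, te) predict(m, te)),
            class = "rpstack_estimator")
}

#' @rdname estimator_rpslearner
#' @param name a base-learner roster name.
#' @export
estimator_base_learner <- function(name, config = rpslearner_config()) {
  force(name)
  fit <- function(tr) {
    seeds <- derive_child_seeds(config$seed, 3)
    pp <- preprocess(tr)
    fused <- fuse_projections(pp$values, config$k, config$m, seeds[1])
    spec <- base_learner_spec(name,
                              hyperparams = config$learner_params[[name]] %||% list(),
                              seed = derive_child_seeds(config$seed + 104729L, 1))
    lrn <- learner_fit(make_learner(spec), fused$values, tr$labels)
    list(lrn = lrn, genes = tr$genes, fit_stats = attr(pp, "fit_stats"),
         rp_master = seeds[1], config = config,
         class_order = levels(tr$labels))
  }
  pred <- function(m, te) {
    te <- align_genes(m, te)
    pp <- preprocess(te, m$fit_stats)
    fused <- fuse_projections(pp$values, m$config$k, m$config$m, m$rp_master)
    P <- learner_predict_proba(m$lrn, fused$values)[, m$class_order, drop = FALSE]
    pick <- max.col(P, ties.method = "first")
    out <- data.frame(sample = te$samples,
                      label = factor(m$class_order[pick], levels = m$class_order))
    colnames(P) <- paste0("prob_", m$class_order)
    cbind(out, as.data.frame(P))
  }
  structure(list(name = name, fit = fit, predict = pred),
            class = "rpstack_estimator")
}

#' @rdname estimator_rpslearner
#' @param classifier `"svm"` (linear, Pegasos-trained) or `"rf"`.
#' @param n_features genes kept by ANOVA-F selection on the training fold.
#' @export
estimator_anova <- function(classifier = c("svm", "rf"), n_features = 1000,
                            config = rpslearner_config()) {
  classifier <- match.arg(classifier)
  fit <- function(tr) {
    pp <- preprocess(tr)
    sel <- anova_select(pp, n_features)
    model <- if (classifier == "svm") {
      linear_svm_fit(sel$values, tr$labels, seed = config$seed)
    } else {
      learner_fit(make_learner(base_learner_spec(
        "RF-G", hyperparams = config$learner_params[["RF-G"]] %||% list(),
        seed = config$seed)), sel$values, tr$labels)
    }
    list(model = model, classifier = classifier, genes = tr$genes,
         keep = sel$genes, fit_stats = attr(pp, "fit_stats"),
         class_order = levels(tr$labels))
  }
  pred <- function(m, te) {
    te <- align_genes(m, te)
    pp <- preprocess(te, m$fit_stats)
    Xk <- pp$values[, m$keep, drop = FALSE]
    P <- if (m$classifier == "svm") linear_svm_predict_proba(m$model, Xk)
         else learner_predict_proba(m$model, Xk)
    P <- P[, m$class_order, drop = FALSE]
    pick <- max.col(P, ties.method = "first")
    out <- data.frame(sample = te$samples,
                      label = factor(m$class_order[pick], levels = m$class_order))
    colnames(P) <- paste0("prob_", m$class_order)
    cbind(out, as.data.frame(P))
  }
  structure(list(name = paste0("anova_", classifier), fit = fit, predict = pred),
            class = "rpstack_estimator")
}

#' Repeated stratified K-fold cross-validation benchmark
#'
#' For each repeat a fresh seeded stratified K-fold split is drawn; every
#' estimator in the list is fitted on each training fold (all preprocessing,
#' projection and out-of-fold machinery happens inside the fold) and scored
#' on the held-out fold. All estimators share identical fold splits within a
#' run (paired design), so per-fold metric differences are directly
#' comparable with [paired_compare()].
#'
#' @param estimators a single estimator or list of estimators (see
#'   [estimator_rpslearner()]).
#' @param ds labelled [expr_dataset()], `scale = "tpm"`.
#' @param repeats number of CV repeats `r >= 1`.
#' @param folds `K >= 2`; every class needs at least `K` members.
#' @param seed master seed; repeat `i` uses derived seed `i`.
#' @return a `metrics_table` data.frame with columns `estimator`, `rep`,
#'   `fold`, `accuracy`, `f1`, `mcc`, `auc`; attributes `repeats`, `folds`,
#'   `seed` and `fold_ids` (list of per-repeat assignments).
#' @export
repeated_cv <- function(estimators, ds, repeats = 10, folds = 5, seed = 0) {
  if (inherits(estimators, "rpstack_estimator")) estimators <- list(estimators)
  repeats <- check_count(repeats, "repeats")
  folds <- check_count(folds, "folds")
  if (folds < 2) abort("'folds' must be >= 2")
  if (is.null(ds$labels)) abort("dataset has no labels")
  rseeds <- derive_child_seeds(seed, repeats)
  positive <- sort(levels(ds$labels))[nlevels(ds$labels)]
  rows <- list()
  fold_ids <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(ds$labels, folds, rseeds[r])
    fold_ids[[r]] <- fold
    for (f in seq_len(folds)) {
      tr <- subset_ds(ds, fold != f)
      te <- subset_ds(ds, fold == f)
      for (est in estimators) {
        model <- est$fit(tr)
        pred <- est$predict(model, te)
        m <- compute_metrics(te$labels, pred$label,
                             pred[[paste0("prob_", positive)]], positive)
        rows[[length(rows) + 1]] <- data.frame(
          estimator = est$name, rep = r, fold = f, accuracy = m["accuracy"],
          f1 = m["f1"], mcc = m["mcc"], auc = m["auc"], row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_table", class(out))
  attr(out, "repeats") <- repeats
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  attr(out, "fold_ids") <- fold_ids
  out
}

subset_ds <- function(ds, keep) {
  out <- ds
  out$values <- ds$values[keep, , drop = FALSE]
  out$samples <- ds$samples[keep]
  if (!is.null(ds$labels)) out$labels <- factor(ds$labels[keep])
  attr(out, "truth") <- NULL
  out
}

#' Paired significance comparison with star annotations
#'
#' Two-sided paired Wilcoxon signed-rank test over the `r * K` per-fold
#' metric values of two estimators benchmarked in the same [repeated_cv()]
#' run. Stars follow the conventional thresholds: `ns` for p >= 0.05, `*`
#' for p < 0.05, `**` for p < 0.01, `***` for p < 0.001. Identical metric
#' vectors (all differences zero) return p = 1, `ns`.
#'
#' @param table a [repeated_cv()] metrics table.
#' @param estimatorA,estimatorB estimator names present in the table.
#' @param metric one of `"accuracy"`, `"f1"`, `"mcc"`, `"auc"`.
#' @return list with `p_value`, `stars`, `mean_a`, `mean_b`.
#' @export
paired_compare <- function(table, estimatorA, estimatorB, metric = "accuracy") {
  a <- table[table$estimator == estimatorA, ]
  b <- table[table$estimator == estimatorB, ]
  if (nrow(a) == 0 || nrow(b) == 0) abort("estimator not present in table")
  a <- a[order(a$rep, a$fold), ]
  b <- b[order(b$rep, b$fold), ]
  if (!identical(a$rep, b$rep) || !identical(a$fold, b$fold))
    abort("records are not paired: fold structures differ")
  x <- a[[metric]]; y <- b[[metric]]
  d <- x - y
  if (all(d == 0)) {
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                      alternative = "two.sided"))$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(p_value = p, stars = stars, mean_a = mean(x), mean_b = mean(y))
}

#' Hyperparameter sweep over projection dimension and count
#'
#' Runs [repeated_cv()] of the stacked pipeline at every `(k, m)` grid point
#' with a shared master seed, so fold structure is identical across grid
#' points. Default grid mirrors the reference ranges: projected dimension
#' 100-1400 and up to 30 projections (performance typically plateaus around
#' k = 400 and ~25 projections).
#'
#' @param ds labelled [expr_dataset()].
#' @param ks,ms grids of projected dimension and projection count.
#' @param repeats,folds,seed as in [repeated_cv()].
#' @param config base configuration; `k`/`m` are overridden per grid point.
#' @return a `metrics_table` with additional columns `k` and `m`.
#' @export
sweep_rp <- function(ds, ks = c(100, 200, 400, 800, 1400),
                     ms = c(1, 5, 10, 25, 30), repeats = 3, folds = 5,
                     seed = 0, config = rpslearner_config()) {
  if (!length(ks) || !length(ms)) abort("empty sweep grid")
  out <- list()
  for (k in ks) for (m in ms) {
    cfg <- config
    cfg$k <- as.integer(k); cfg$m <- as.integer(m)
    tab <- repeated_cv(estimator_rpslearner(cfg), ds, repeats, folds, seed)
    tab$k <- k; tab$m <- m
    out[[length(out) + 1]] <- tab
  }
  res <- do.call(rbind, out)
  class(res) <- c("metrics_table", "data.frame")
  res
}

#' Select genes by one-way ANOVA F statistic
#'
#' Ranks genes by the between-class F statistic computed on the supplied
#' (training) data and keeps the top `n_features`. In the two-class
#' equal-variance case F equals the squared two-sample t statistic.
#'
#' @param ds labelled [expr_dataset()] (any scale; the stored values are
#'   used as-is, so pass preprocessed data for comparator pipelines).
#' @param n_features number of genes to keep, `1 <= n_features <= d`.
#' @return an [expr_dataset()] reduced to the selected genes (ranking order
#'   preserved in attribute `"F_stat"`).
#' @export
anova_select <- function(ds, n_features) {
  if (is.null(ds$labels)) abort("anova_select needs labels")
  n_features <- check_count(n_features, "n_features")
  if (n_features > length(ds$genes)) abort("'n_features' exceeds gene count")
  F <- anova_f(ds$values, ds$labels)
  keep <- order(-F)[seq_len(n_features)]
  keep <- sort(keep)  # preserve gene order for readability
  out <- subset_genes(ds, keep)
  attr(out, "F_stat") <- F[keep]
  out
}

anova_f <- function(X, labels) {
  labels <- factor(labels)
  n <- nrow(X); g <- nlevels(labels)
  grand <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (cl in levels(labels)) {
    idx <- labels == cl
    m <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (m - grand)^2
    ssw <- ssw + colSums(sweep(X[idx, , drop = FALSE], 2, m)^2)
  }
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
}

subset_genes <- function(ds, keep) {
  out <- ds
  out$values <- ds$values[, keep, drop = FALSE]
  out$genes <- ds$genes[keep]
  out
}

#' Label-based differential expression
#'
#' Generic two-group DE given any label assignment (typically a classifier's
#' predictions): per gene, the log2 fold-change of class means on the
#' `log2(TPM + 1)` scale, a two-sided Wilcoxon rank-sum p-value (normal
#' approximation with tie correction and continuity correction), and
#' Benjamini-Hochberg q-values.
#'
#' @param ds an [expr_dataset()], `scale = "tpm"` (transformed internally)
#'   or `"log2tpm"` (used as stored).
#' @param predicted_labels two-class label vector aligned with samples.
#' @param alpha FDR threshold for the `significant` flag.
#' @return data.frame `(gene, log2FC, p, q, significant)`; `log2FC > 0`
#'   means higher in the lexicographically first class.
#' @export
label_based_de <- function(ds, predicted_labels, alpha = 0.05) {
  labels <- factor(as.character(predicted_labels))
  if (nlevels(labels) != 2) abort("need exactly two predicted classes")
  if (any(table(labels) < 3))
    abort("class '", names(which(table(labels) < 3))[1], "' has fewer than 3 samples")
  lv <- if (ds$scale == "tpm") log2(ds$values + 1) else ds$values
  g1 <- labels == levels(labels)[1]
  lfc <- colMeans(lv[g1, , drop = FALSE]) - colMeans(lv[!g1, , drop = FALSE])
  p <- ranksum_p(lv, g1)
  q <- p.adjust(p, method = "BH")
  data.frame(gene = ds$genes, log2FC = lfc, p = p, q = q,
             significant = q < alpha, row.names = NULL)
}

# vectorised two-sided rank-sum p over all genes (columns)
ranksum_p <- function(X, grp1) {
  n1 <- sum(grp1); n2 <- sum(!grp1); n <- n1 + n2
  p <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    r <- rank(X[, j])
    W <- sum(r[grp1]) - n1 * (n1 + 1) / 2
    ties <- table(X[, j])
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { p[j] <- 1; next }
    z <- (abs(W - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    p[j] <- min(1, 2 * pnorm(-max(z, 0)))
  }
  p
}
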