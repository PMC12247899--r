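#' Pipeline configuration
#'
#' Defaults follow the reference setting for the method: `m = 20` independent
#' `k = 400`-dimensional projections, all ten base learners, 5 inner folds for
#' out-of-fold meta-features, and a (256, 64) ReLU MLP meta-learner.
#'
#' @param k projected dimension per random projection.
#' @param m number of independent projections fused by concatenation.
#' @param learners character vector of roster names (see
#'   [base_learner_spec()]); order fixes the meta-feature block order.
#' @param n_inner_folds inner folds for out-of-fold base predictions.
#' @param meta_hidden hidden layer sizes of the meta-MLP.
#' @param meta_activation `"relu"` (default) or `"linear"` (a pure linear
#'   stack of layers; "deep linear network" admits either reading).
#' @param append_raw if `TRUE` the composite appends the raw preprocessed
#'   d-dimensional profile instead of the fused projections (fidelity mode;
#'   the default fused mode keeps the dimensionality-reduction premise).
#' @param hard_labels if `TRUE` base meta-features are one-hot predicted
#'   labels rather than probabilities (fidelity mode).
#' @param ensemble_learner classifier used per projection by the
#'   score-ensemble baseline (default `"NN"`, the strongest single model).
#' @param learner_params named list (by learner name) of hyperparameter
#'   overrides, e.g. `list("RF-G" = list(n_trees = 100))`.
#' @param meta_params overrides for the meta-MLP optimiser
#'   (`max_epochs`, `lr`, `weight_decay`, `patience`).
#' @param seed master seed; all stage seeds are derived from it.
#' @return a `rpslearner_config` list.
#' @export
rpslearner_config <- function(k = 400, m = 20, learners = LEARNER_NAMES,
                              n_inner_folds = 5, meta_hidden = c(256, 64),
                              meta_activation = c("relu", "linear"),
                              append_raw = FALSE, hard_labels = FALSE,
                              ensemble_learner = "NN", learner_params = list(),
                              meta_params = list(), seed = 0) {
  meta_activation <- match.arg(meta_activation)
  bad <- setdiff(learners, LEARNER_NAMES)
  if (length(bad)) abort("unknown learner(s): ", paste(bad, collapse = ", "))
  structure(list(k = check_count(k, "k"), m = check_count(m, "m"),
                 learners = learners, n_inner_folds = n_inner_folds,
                 meta_hidden = meta_hidden, meta_activation = meta_activation,
                 append_raw = append_raw, hard_labels = hard_labels,
                 ensemble_learner = ensemble_learner,
                 learner_params = learner_params, meta_params = meta_params,
                 seed = as.integer(seed)),
            class = "rpslearner_config")
}

as_hard_labels <- function(proba, C) {
  # one-hot argmax per learner block (ties to the first class in order)
  out <- proba * 0
  N <- ncol(proba) / C
  for (j in seq_len(N)) {
    cols <- ((j - 1) * C + 1):(j * C)
    pick <- max.col(proba[, cols, drop = FALSE], ties.method = "first")
    out[cbind(seq_len(nrow(proba)), cols[pick])] <- 1
  }
  out
}

#' Build the composite meta-feature matrix z(x)
#'
#' Column-wise concatenation of the fused projection features with the base
#' prediction blocks, `z(x) = (x, p1, ..., pN)`; no value is altered and the
#' block layout is recorded so any block can be recovered exactly.
#'
#' @param fused a [fuse_projections()] result (or plain matrix) over the
#'   same samples, in the same order, as `preds`.
#' @param preds a [out_of_fold_predict()] block, or `NULL` for no learners.
#' @return object of class `composite_features`: list with `values`,
#'   `layout` (named list of column index vectors).
#' @export
build_composite <- function(fused, preds = NULL) {
  fv <- if (inherits(fused, "fused_features")) fused$values else as.matrix(fused)
  if (is.null(preds)) {
    return(structure(list(values = fv, layout = list(fused = seq_len(ncol(fv)))),
                     class = "composite_features"))
  }
  if (nrow(fv) != nrow(preds$proba))
    abort("sample-count mismatch: fused has ", nrow(fv), " rows, predictions ",
          nrow(preds$proba))
  values <- cbind(fv, preds$proba)
  C <- length(preds$class_order)
  layout <- c(list(fused = seq_len(ncol(fv))),
              stats::setNames(lapply(seq_along(preds$learner_names), function(j)
                ncol(fv) + ((j - 1) * C + 1):(j * C)), preds$learner_names))
  structure(list(values = values, layout = layout), class = "composite_features")
}

#' Train the MLP meta-learner on composite features
#'
#' Feed-forward network (default two hidden layers of 256 and 64 ReLU units),
#' softmax output, cross-entropy loss, full-batch Adam, early stopping on a
#' 10\% stratified validation split, seeded initialisation.
#'
#' @param Z a [build_composite()] result or plain matrix.
#' @param labels class labels aligned with the rows of `Z`.
#' @param config a [rpslearner_config()] (meta_* fields are used).
#' @return object of class `meta_model` wrapping the network and class order.
#' @export
train_meta <- function(Z, labels, config = rpslearner_config()) {
  zv <- if (inherits(Z, "composite_features")) Z$values else as.matrix(Z)
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("need at least 2 classes to train the meta-learner")
  if (nrow(zv) != length(labels)) abort("Z rows do not match labels")
  mp <- config$meta_params
  net <- mlp_fit(zv, labels, hidden = config$meta_hidden,
                 activation = config$meta_activation,
                 max_epochs = mp$max_epochs %||% 300, lr = mp$lr %||% 1e-2,
                 weight_decay = mp$weight_decay %||% 1e-4,
                 patience = mp$patience %||% 25,
                 seed = derive_child_seeds(config$seed, 3)[3])
  structure(list(network = net, class_order = levels(labels)),
            class = "meta_model")
}

#' @export
predict.meta_model <- function(object, newdata, ...) {
  P <- mlp_predict_proba(object$network, newdata)
  P[, object$class_order, drop = FALSE]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort(name, ": ", conditionMessage(e)))
}

#' Fit the full random-projection stacking pipeline
#'
#' Training-data-only sequence: preprocess (log2(TPM+1) + per-gene z-score)
#' -> fuse `m` independent `k`-dimensional Gaussian projections ->
#' out-of-fold base-learner probabilities -> composite features -> MLP
#' meta-learner. Every base learner is additionally refit on the full
#' training set; those full-fit learners produce the prediction blocks at
#' test time (standard stacked-generalisation practice). All seeds, gene
#' statistics and projection seeds are stored for exact test-time
#' reproduction.
#'
#' @param ds a labelled [expr_dataset()] with `scale = "tpm"`.
#' @param config a [rpslearner_config()].
#' @return object of class `rpslearner`.
#' @export
fit_rpslearner <- function(ds, config = rpslearner_config()) {
  if (!inherits(ds, "expr_dataset")) abort("'ds' must be an expr_dataset")
  if (is.null(ds$labels)) abort("fit_rpslearner: dataset has no labels")
  if (ds$scale == "counts")
    abort("fit_rpslearner: convert counts with counts_to_tpm() first")
  if (ds$scale != "tpm") abort("fit_rpslearner: expected scale 'tpm'")
  seeds <- derive_child_seeds(config$seed, 3)  # rp, oof, meta

  pp <- stage("preprocess", preprocess(ds))
  fused <- stage("fuse_projections",
                 fuse_projections(pp$values, config$k, config$m, seeds[1]))
  specs <- roster_specs(config)
  preds <- stage("out_of_fold_predict",
                 out_of_fold_predict(fused$values, ds$labels, specs,
                                     config$n_inner_folds, seeds[2]))
  C <- length(preds$class_order)
  if (config$hard_labels) preds$proba <- as_hard_labels(preds$proba, C)
  xpart <- if (config$append_raw) pp$values else fused
  Z <- stage("build_composite", build_composite(xpart, preds))
  meta <- stage("train_meta", train_meta(Z, ds$labels, config))
  full_fit <- stage("base_refit", lapply(specs, function(s)
    learner_fit(make_learner(s), fused$values, ds$labels)))

  structure(list(format = "rpslearner/1",
                 config = config,
                 genes = ds$genes,
                 fit_stats = attr(pp, "fit_stats"),
                 rp_seeds = fused$seeds,
                 base_learners = full_fit,
                 meta = meta,
                 class_order = meta$class_order),
            class = "rpslearner")
}

roster_specs <- function(config) {
  seeds <- derive_child_seeds(config$seed + 104729L, length(config$learners))
  lapply(seq_along(config$learners), function(i)
    base_learner_spec(config$learners[i],
                      hyperparams = config$learner_params[[config$learners[i]]] %||% list(),
                      seed = seeds[i]))
}

align_genes <- function(pipeline, ds_new) {
  missing <- setdiff(pipeline$genes, ds_new$genes)
  if (length(missing))
    abort("gene-set mismatch; missing genes: ",
          paste(head(missing, 10), collapse = ", "),
          if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  ds_new$values <- ds_new$values[, pipeline$genes, drop = FALSE]
  ds_new$genes <- pipeline$genes
  ds_new
}

new_feature_path <- function(pipeline, ds_new) {
  ds_new <- align_genes(pipeline, ds_new)
  if (ds_new$scale != "tpm") abort("new data must be TPM scale")
  pp <- preprocess(ds_new, pipeline$fit_stats)
  cfg <- pipeline$config
  fused <- matrix(0, nrow(pp$values), cfg$m * cfg$k)
  for (j in seq_len(cfg$m)) {  # regenerate the stored projections bit-identically
    R <- generate_projection(length(pipeline$genes), cfg$k, pipeline$rp_seeds[j])
    fused[, ((j - 1) * cfg$k + 1):(j * cfg$k)] <- pp$values %*% R$entries
  }
  list(pp = pp, fused = fused)
}

#' Predict subtypes with a fitted pipeline
#'
#' Applies the stored preprocessing statistics, regenerates the stored
#' projection matrices from their seeds, obtains full-fit base-learner
#' probabilities, and evaluates the meta-MLP. The predicted label is the
#' probability argmax; ties break to the first class in the stored class
#' order.
#'
#' @param object a fitted [fit_rpslearner()] pipeline.
#' @param newdata an [expr_dataset()] with `scale = "tpm"` whose genes cover
#'   the training gene set (reordered by identifier; missing genes error).
#' @param ... unused.
#' @return data.frame with `sample`, `label`, and one probability column per
#'   class.
#' @export
predict.rpslearner <- function(object, newdata, ...) {
  fp <- new_feature_path(object, newdata)
  C <- length(object$class_order)
  proba <- do.call(cbind, lapply(object$base_learners, function(l)
    learner_predict_proba(l, fp$fused)))
  if (object$config$hard_labels) proba <- as_hard_labels(proba, C)
  xpart <- if (object$config$append_raw) fp$pp$values else fp$fused
  Z <- cbind(xpart, proba)
  P <- predict(object$meta, Z)
  pick <- max.col(P, ties.method = "first")
  out <- data.frame(sample = newdata$samples,
                    label = factor(object$class_order[pick],
                                   levels = object$class_order),
                    stringsAsFactors = FALSE)
  colnames(P) <- paste0("prob_", object$class_order)
  cbind(out, as.data.frame(P))
}

#' @rdname predict.rpslearner
#' @param pipeline fitted pipeline.
#' @param ds_new new dataset.
#' @export
predict_rpslearner <- function(pipeline, ds_new) predict(pipeline, ds_new)

#' Fit the score-ensemble baseline
#'
#' The conventional alternative to feature fusion: for each of the `m`
#' projections independently, one classifier (default the NN base learner)
#' is trained on that single k-dimensional projection; prediction averages
#' the `m` probability vectors without weights and takes the argmax.
#'
#' @param ds labelled [expr_dataset()], `scale = "tpm"`.
#' @param config a [rpslearner_config()]; `ensemble_learner` selects the
#'   per-projection classifier.
#' @return object of class `score_ensemble`.
#' @export
fit_score_ensemble <- function(ds, config = rpslearner_config()) {
  if (is.null(ds$labels)) abort("fit_score_ensemble: dataset has no labels")
  if (ds$scale != "tpm") abort("fit_score_ensemble: expected scale 'tpm'")
  seeds <- derive_child_seeds(config$seed, 3)
  pp <- preprocess(ds)
  rp_seeds <- derive_child_seeds(seeds[1], config$m)
  lseeds <- derive_child_seeds(config$seed + 7919L, config$m)
  members <- lapply(seq_len(config$m), function(j) {
    R <- generate_projection(ncol(pp$values), config$k, rp_seeds[j])
    spec <- base_learner_spec(config$ensemble_learner,
                              hyperparams = config$learner_params[[config$ensemble_learner]] %||% list(),
                              seed = lseeds[j])
    learner_fit(make_learner(spec), pp$values %*% R$entries, ds$labels)
  })
  structure(list(format = "score_ensemble/1", config = config,
                 genes = ds$genes, fit_stats = attr(pp, "fit_stats"),
                 rp_seeds = rp_seeds, members = members,
                 class_order = levels(ds$labels)),
            class = "score_ensemble")
}

#' @export
predict.score_ensemble <- function(object, newdata, ...) {
  nd <- align_genes(object, newdata)
  pp <- preprocess(nd, object$fit_stats)
  cfg <- object$config
  P <- 0
  for (j in seq_len(cfg$m)) {
    R <- generate_projection(length(object$genes), cfg$k, object$rp_seeds[j])
    P <- P + learner_predict_proba(object$members[[j]], pp$values %*% R$entries)
  }
  P <- P / cfg$m
  P <- P[, object$class_order, drop = FALSE]
  pick <- max.col(P, ties.method = "first")
  out <- data.frame(sample = newdata$samples,
                    label = factor(object$class_order[pick],
                                   levels = object$class_order),
                    stringsAsFactors = FALSE)
  colnames(P) <- paste0("prob_", object$class_order)
  cbind(out, as.data.frame(P))
}

#' Train-and-predict convenience for the score-ensemble baseline
#' @param ds training dataset.
#' @param config pipeline configuration.
#' @param ds_new dataset to predict (defaults to `ds`).
#' @return prediction data.frame as in [predict.rpslearner()].
#' @export
score_ensemble_predict <- function(ds, config = rpslearner_config(), ds_new = ds) {
  predict(fit_score_ensemble(ds, config), ds_new)
}

#' Save / load a fitted pipeline
#'
#' Single-file serialisation of the versioned model object (config, seeds,
#' preprocessing statistics, base-learner parameters, meta-network weights).
#' Identical training inputs and seeds produce byte-identical files.
#'
#' @param model a fitted `rpslearner` or `score_ensemble`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  if (is.null(model$format)) abort("not a serialisable rpstack model")
  saveRDS(model, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (is.null(model$format) || !grepl("^(rpslearner|score_ensemble)/", model$format))
    abort("'", path, "' is not an rpstack model file")
  model
}
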