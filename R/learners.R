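#' The ten base-classifier configurations
#'
#' Roster identifiers follow the usual shorthand for the heterogeneous zoo:
#' \describe{
#'   \item{KNN-D / KNN-U}{k-nearest neighbours (default k = 5), distance
#'     weighted / uniform votes. Neighbour search via \pkg{FNN}.}
#'   \item{RF-G / RF-E}{random forest (bootstrap, sqrt(p) features per node),
#'     gini / entropy split criterion; default 500 trees.}
#'   \item{ET-G / ET-E}{extremely randomised trees (no bootstrap, one random
#'     threshold per candidate feature), gini / entropy; default 500 trees.}
#'   \item{XGB}{gradient-boosted trees, depth-wise growth with second-order
#'     gains (XGBoost-style); 200 rounds, depth 6, lr 0.1, lambda 1.}
#'   \item{LGBM}{gradient-boosted trees, leaf-wise (best-first) growth
#'     (LightGBM-style); 200 rounds, 31 leaves, lr 0.1.}
#'   \item{CB}{gradient-boosted oblivious (symmetric) trees
#'     (CatBoost-style); 200 rounds, depth 6, lr 0.1, lambda 3.}
#'   \item{NN}{small feed-forward network, 2 hidden ReLU layers (64, 32),
#'     full-batch Adam with early stopping. Distinct from the meta-MLP.}
#' }
#' Tree engines are implemented in the package (compiled code); none of the
#' upstream boosting libraries is a dependency.
#'
#' @param name one of the roster identifiers above.
#' @param hyperparams named list of overrides of the documented defaults.
#' @param seed integer seed controlling all stochastic elements of the fit.
#' @return object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(name, hyperparams = list(), seed = 0) {
  if (!name %in% LEARNER_NAMES)
    abort("unknown learner '", name, "'; valid names: ",
          paste(LEARNER_NAMES, collapse = ", "))
  structure(list(name = name, hyperparams = hyperparams, seed = as.integer(seed)),
            class = "base_learner_spec")
}

LEARNER_NAMES <- c("KNN-D", "KNN-U", "RF-G", "RF-E", "ET-G", "ET-E",
                   "LGBM", "CB", "XGB", "NN")

#' Default roster of all ten base learners
#' @param seed master seed; each learner gets a distinct derived seed.
#' @param hyperparams named list (by learner name) of override lists.
#' @return list of [base_learner_spec()] in canonical roster order.
#' @export
default_learner_roster <- function(seed = 0, hyperparams = list()) {
  seeds <- derive_child_seeds(seed, length(LEARNER_NAMES))
  lapply(seq_along(LEARNER_NAMES), function(i)
    base_learner_spec(LEARNER_NAMES[i],
                      hyperparams = hyperparams[[LEARNER_NAMES[i]]] %||% list(),
                      seed = seeds[i]))
}

learner_defaults <- function(name) {
  switch(name,
    "KNN-D" = , "KNN-U" = list(n_neighbors = 5),
    "RF-G" = , "RF-E" = list(n_trees = 500, min_node = 2, mtry = NA),
    "ET-G" = , "ET-E" = list(n_trees = 500, min_node = 2, mtry = NA),
    "XGB" = list(n_rounds = 200, lr = 0.1, max_depth = 6, lambda = 1,
                 subsample = 1, colsample = 1, min_child_weight = 1),
    "LGBM" = list(n_rounds = 200, lr = 0.1, max_leaves = 31, lambda = 1,
                  subsample = 1, colsample = 1, min_child_weight = 1e-3),
    "CB" = list(n_rounds = 200, lr = 0.1, max_depth = 6, lambda = 3,
                subsample = 1, colsample = 1, min_child_weight = 1e-3),
    "NN" = list(hidden = c(64, 32), max_epochs = 200, lr = 1e-2,
                weight_decay = 1e-4, patience = 20))
}

#' Instantiate a trainable classifier from a learner spec
#'
#' Returns a handle exposing [learner_fit()] and, once fitted,
#' [learner_predict_proba()]. Behaviour is deterministic under the spec seed.
#'
#' @param spec a [base_learner_spec()] (or a roster name, for convenience).
#' @return object of class `base_learner`.
#' @export
make_learner <- function(spec) {
  if (is.character(spec)) spec <- base_learner_spec(spec)
  if (!inherits(spec, "base_learner_spec")) abort("'spec' must be a base_learner_spec")
  hp <- modifyList(learner_defaults(spec$name), spec$hyperparams)
  structure(list(spec = spec, hp = hp, fitted = NULL), class = "base_learner")
}

#' Fit a base learner
#' @param learner a [make_learner()] handle.
#' @param X `n x p` feature matrix.
#' @param y class labels (factor or coercible).
#' @return the fitted handle.
#' @export
learner_fit <- function(learner, X, y) {
  stopifnot(inherits(learner, "base_learner"))
  X <- as.matrix(X)
  y <- factor(y)
  name <- learner$spec$name
  hp <- learner$hp
  seed <- learner$spec$seed
  fitted <- switch(sub("-[DUGE]$", "", name),
    "KNN" = list(X = X, y = y),
    "RF" = , "ET" = {
      mtry <- if (is.na(hp$mtry)) max(1L, floor(sqrt(ncol(X)))) else as.integer(hp$mtry)
      trees <- .cpp_forest_fit(X, as.integer(y) - 1L, nlevels(y),
                               as.integer(hp$n_trees), mtry,
                               as.integer(hp$min_node),
                               criterion = if (grepl("-E$", name)) 1L else 0L,
                               splitter = if (startsWith(name, "ET")) 1L else 0L,
                               bootstrap = startsWith(name, "RF"),
                               seed = seed)
      list(trees = trees, classes = levels(y))
    },
    "XGB" = , "LGBM" = , "CB" = {
      growth <- switch(name, XGB = 0L, LGBM = 1L, CB = 2L)
      fit_one <- function(y01, s)
        .cpp_gbdt_fit(X, y01, as.integer(hp$n_rounds), hp$lr,
                      as.integer(hp$max_depth %||% 6),
                      as.integer(hp$max_leaves %||% 31), growth, hp$lambda,
                      hp$subsample, hp$colsample, hp$min_child_weight,
                      64L, s)
      if (nlevels(y) == 2) {
        list(model = fit_one(as.numeric(y == levels(y)[2]), seed),
             classes = levels(y), binary = TRUE)
      } else {  # one-vs-rest, normalised
        seeds <- derive_child_seeds(seed, nlevels(y))
        models <- lapply(seq_len(nlevels(y)), function(c)
          fit_one(as.numeric(y == levels(y)[c]), seeds[c]))
        list(models = models, classes = levels(y), binary = FALSE)
      }
    },
    "NN" = mlp_fit(X, y, hidden = hp$hidden, activation = "relu",
                   max_epochs = hp$max_epochs, lr = hp$lr,
                   weight_decay = hp$weight_decay, patience = hp$patience,
                   seed = seed))
  learner$fitted <- fitted
  learner$classes <- levels(y)
  learner
}

#' Predict class probabilities from a fitted base learner
#' @param learner a fitted [learner_fit()] handle.
#' @param X feature matrix with the training column count.
#' @return `n x C` probability matrix, columns named by class, rows summing
#'   to 1.
#' @export
learner_predict_proba <- function(learner, X) {
  stopifnot(inherits(learner, "base_learner"))
  if (is.null(learner$fitted)) abort("learner has not been fitted")
  X <- as.matrix(X)
  name <- learner$spec$name
  f <- learner$fitted
  P <- switch(sub("-[DUGE]$", "", name),
    "KNN" = {
      k <- min(learner$hp$n_neighbors, nrow(f$X))
      nn <- FNN::get.knnx(f$X, X, k = k)
      C <- nlevels(f$y)
      w <- if (name == "KNN-D") 1 / (nn$nn.dist + 1e-8) else
        matrix(1, nrow(X), k)
      P <- matrix(0, nrow(X), C)
      lab <- matrix(as.integer(f$y)[nn$nn.index], nrow(X), k)
      for (c in seq_len(C)) P[, c] <- rowSums(w * (lab == c))
      P <- P / rowSums(P)
      colnames(P) <- levels(f$y)
      P
    },
    "RF" = , "ET" = {
      P <- .cpp_forest_predict(f$trees, X, length(f$classes))
      colnames(P) <- f$classes
      P
    },
    "XGB" = , "LGBM" = , "CB" = {
      if (f$binary) {
        p2 <- stats::plogis(.cpp_gbdt_predict(f$model, X))
        P <- cbind(1 - p2, p2)
      } else {
        P <- vapply(f$models, function(m) stats::plogis(.cpp_gbdt_predict(m, X)),
                    numeric(nrow(X)))
        P <- matrix(P, nrow(X))
        P <- P / rowSums(P)
      }
      colnames(P) <- f$classes
      P
    },
    "NN" = mlp_predict_proba(f, X))
  P
}

#' Leakage-safe out-of-fold base-learner predictions
#'
#' Stratified partition into `n_inner_folds`; each learner is trained on each
#' fold complement and predicts class probabilities for the held-out fold, so
#' every sample's meta-feature row comes from a model that never saw that
#' sample. Fold assignment depends only on the label vector, `n_inner_folds`
#' and `seed`.
#'
#' @param features `n x p` matrix.
#' @param labels per-sample class labels.
#' @param specs list of [base_learner_spec()] (or roster names).
#' @param n_inner_folds number of folds, `>= 2`; every class must have at
#'   least this many members.
#' @param seed fold-assignment seed.
#' @param folds optional explicit fold assignment (integer vector in
#'   `1..n_inner_folds` per sample), overriding the seeded stratified split;
#'   useful for leakage audits where labels are mutated while the partition
#'   is held fixed.
#' @return object of class `base_prediction_block`: list with `proba`
#'   (`n x (N*C)`, learner-blocked in spec order), `learner_names`,
#'   `class_order`, `out_of_fold = TRUE`, `folds`.
#' @export
out_of_fold_predict <- function(features, labels, specs, n_inner_folds = 5,
                                seed = 0, folds = NULL) {
  features <- as.matrix(features)
  labels <- factor(labels)
  n_inner_folds <- check_count(n_inner_folds, "n_inner_folds")
  if (n_inner_folds < 2) abort("'n_inner_folds' must be >= 2")
  specs <- lapply(specs, function(s) if (is.character(s)) base_learner_spec(s) else s)
  fold <- folds %||% stratified_folds(labels, n_inner_folds, seed)
  if (length(fold) != nrow(features)) abort("'folds' length must match samples")
  C <- nlevels(labels)
  N <- length(specs)
  proba <- matrix(NA_real_, nrow(features), N * C)
  for (j in seq_len(N)) {
    cols <- ((j - 1) * C + 1):(j * C)
    for (f in seq_len(n_inner_folds)) {
      hold <- fold == f
      lrn <- learner_fit(make_learner(specs[[j]]),
                         features[!hold, , drop = FALSE], labels[!hold])
      proba[hold, cols] <- learner_predict_proba(lrn, features[hold, , drop = FALSE])
    }
  }
  names <- vapply(specs, function(s) s$name, character(1))
  colnames(proba) <- paste(rep(names, each = C), rep(levels(labels), N), sep = ":")
  structure(list(proba = proba, learner_names = names,
                 class_order = levels(labels), out_of_fold = TRUE, folds = fold),
            class = "base_prediction_block")
}

#' Rank base learners from a benchmark metrics table
#'
#' Learners are sorted by mean accuracy (descending); ties are broken by mean
#' F1, then lexicographically by name.
#'
#' @param metrics a [repeated_cv()] metrics table (estimator column holds
#'   learner names).
#' @return character vector of learner names, best first.
#' @export
rank_learners <- function(metrics) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0) abort("empty metrics table")
  agg <- stats::aggregate(metrics[, c("accuracy", "f1")],
                          by = list(name = metrics$estimator), FUN = mean)
  agg$name <- as.character(agg$name)
  agg[order(-agg$accuracy, -agg$f1, agg$name), "name"]
}
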