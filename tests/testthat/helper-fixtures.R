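# Shared fixtures: everything is generated in code at test time.

# small, clearly separable cohort for pipeline smoke tests
tiny_ds <- function(n_per_class = 30, d = 200, n_de = min(40, d %/% 4),
                    lfc = 3, seed = 7) {
  generate_dataset(synthetic_spec(n_per_class = n_per_class, d = d,
                                  n_de = n_de, lfc = lfc, noise_sd = 1,
                                  block_size = min(20, d), rho = 0.3,
                                  seed = seed))
}

# learner sizes scaled down for test runtime; the package defaults stay at
# their documented values (500 trees, 200 rounds, ...)
fast_learner_params <- function() {
  list("RF-G" = list(n_trees = 50), "RF-E" = list(n_trees = 50),
       "ET-G" = list(n_trees = 50), "ET-E" = list(n_trees = 50),
       "XGB" = list(n_rounds = 50, max_depth = 4),
       "LGBM" = list(n_rounds = 50, max_leaves = 15),
       "CB" = list(n_rounds = 50, max_depth = 4),
       "NN" = list(max_epochs = 100))
}

fast_config <- function(k = 30, m = 3, seed = 5,
                        learners = c("KNN-U", "RF-G", "XGB", "NN"), ...) {
  rpslearner_config(k = k, m = m, seed = seed, learners = learners,
                    learner_params = fast_learner_params(),
                    meta_hidden = c(32, 16),
                    meta_params = list(max_epochs = 150), ...)
}

split_ds <- function(ds, test_frac = 0.25, seed = 99) {
  fold <- stratified_folds(ds$labels, round(1 / test_frac), seed)
  list(train = rpstack:::subset_ds(ds, fold != 1),
       test = rpstack:::subset_ds(ds, fold == 1))
}
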