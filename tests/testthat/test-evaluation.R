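test_that("metrics match hand-computed confusion arithmetic", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), c(.9, .8, .2, .1), positive = "1")
  expect_equal(unname(m), c(1, 1, 1, 1))
  # TP=1 FN=1 TN=2 FP=0
  m2 <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = "1")
  expect_equal(m2[["accuracy"]], 0.75)
  expect_equal(m2[["mcc"]], 2 / sqrt(12))
  # reversed ranking of a perfect AUC case
  m3 <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), c(.1, .2, .8, .9), positive = "1")
  expect_equal(m3[["auc"]], 0)
  # single-class truth: AUC undefined, flagged
  m4 <- compute_metrics(c(1, 1), c(1, 0), c(.5, .4), positive = "1")
  expect_true(is.na(m4[["auc"]]))
  expect_true(attr(m4, "auc_undefined"))
})

test_that("metrics agree with the brute-force oracle on random short cases", {
  withr::with_seed(42, {
    for (case in 1:300) {
      n <- sample(2:8, 1)
      y_true <- sample(c("n", "p"), n, replace = TRUE)
      y_pred <- sample(c("n", "p"), n, replace = TRUE)
      prob <- round(runif(n), 2)  # rounding provokes ties
      got <- compute_metrics(y_true, y_pred, prob, positive = "p")
      want <- oracle_metrics(y_true, y_pred, prob, positive = "p")
      expect_equal(got[["accuracy"]], want[["accuracy"]])
      expect_equal(got[["f1"]], want[["f1"]])
      expect_equal(got[["mcc"]], want[["mcc"]])
      if (!is.na(want[["auc"]])) expect_equal(got[["auc"]], want[["auc"]])
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(7, {
    y <- sample(c("a", "b"), 30, replace = TRUE)
    p <- runif(30)
  })
  a1 <- compute_metrics(y, y, p, positive = "b")[["auc"]]
  a2 <- compute_metrics(y, y, exp(3 * p) - 1, positive = "b")[["auc"]]
  expect_equal(a1, a2)
})

# deterministic stub estimators for harness tests
stub_estimator <- function(name, predictor) {
  structure(list(name = name,
                 fit = function(tr) list(classes = levels(tr$labels)),
                 predict = function(m, te) {
                   P <- predictor(te, m$classes)
                   pick <- max.col(P, ties.method = "first")
                   out <- data.frame(sample = te$samples,
                                     label = factor(m$classes[pick], levels = m$classes))
                   colnames(P) <- paste0("prob_", m$classes)
                   cbind(out, as.data.frame(P))
                 }),
            class = "rpstack_estimator")
}

test_that("repeated_cv bookkeeping, base-rate sanity and paired folds", {
  ds <- tiny_ds(n_per_class = 25, d = 30, seed = 2)
  # constant majority-class predictor on a 60/40 split of the binary labels
  ds40 <- rpstack:::subset_ds(ds, c(rep(TRUE, 25), rep(c(TRUE, FALSE, FALSE, FALSE, TRUE), 5)))
  const <- stub_estimator("const", function(te, cl)
    matrix(rep(c(1, 0), each = length(te$samples)), ncol = 2))
  oracle_lab <- stub_estimator("oracle", function(te, cl) {
    P <- matrix(0, length(te$samples), 2)
    P[cbind(seq_along(te$labels), as.integer(te$labels))] <- 1
    P
  })
  tab <- repeated_cv(list(const, oracle_lab), ds40, repeats = 2, folds = 5, seed = 3)
  expect_equal(nrow(tab), 2 * 2 * 5)
  expect_equal(sum(tab$estimator == "const"), 10)
  expect_lt(abs(mean(tab$accuracy[tab$estimator == "const"]) - 25 / 35), 0.06)
  expect_equal(mean(tab$accuracy[tab$estimator == "oracle"]), 1)
  # estimators share identical fold splits (paired design)
  expect_length(attr(tab, "fold_ids"), 2)
  pc <- paired_compare(tab, "oracle", "oracle")
  expect_equal(pc$p_value, 1)
  expect_identical(pc$stars, "ns")
})

test_that("paired_compare matches the enumerated signed-rank distribution", {
  accA <- c(0.91, 0.83, 0.95, 0.88, 0.79, 0.97)
  accB <- c(0.85, 0.86, 0.90, 0.80, 0.78, 0.90)
  tab <- data.frame(estimator = rep(c("A", "B"), each = 6), rep = 1,
                    fold = rep(1:6, 2), accuracy = c(accA, accB),
                    f1 = 0, mcc = 0, auc = 0.5)
  pc <- paired_compare(tab, "A", "B", "accuracy")
  expect_equal(pc$p_value, oracle_signed_rank_p(accA - accB), tolerance = 1e-12)
  # star thresholds
  stars_for <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "ns"
  expect_identical(pc$stars, stars_for(pc$p_value))
  expect_identical(stars_for(0.004), "**")
  expect_error(paired_compare(tab[-1, ], "A", "B"), "paired")
})

test_that("ANOVA selection finds planted genes and honours its identities", {
  ds <- generate_dataset(synthetic_spec(n_per_class = 50, d = 400, n_de = 20,
                                        lfc = 4, noise_sd = 1, seed = 12))
  pp <- preprocess(ds)
  truth <- attr(ds, "truth")
  sel <- anova_select(pp, 20)
  expect_gte(length(intersect(match(sel$genes, ds$genes), truth$de_genes)), 19)
  # n_features = d is the identity on the gene set
  expect_identical(anova_select(pp, 400)$genes, pp$genes)
  # two-class F equals the squared pooled-variance t statistic
  g1 <- ds$labels == levels(ds$labels)[1]
  v <- pp$values[, 5]
  tt <- t.test(v[g1], v[!g1], var.equal = TRUE)$statistic
  Fv <- rpstack:::anova_f(pp$values[, 5, drop = FALSE], ds$labels)
  expect_equal(unname(Fv), unname(tt^2))
})

test_that("label-based DE flags planted genes and returns symmetric nulls", {
  ds <- generate_dataset(synthetic_spec(n_per_class = 100, d = 300, n_de = 10,
                                        lfc = 4, noise_sd = 1, seed = 14))
  truth <- attr(ds, "truth")
  de <- label_based_de(ds, ds$labels, alpha = 0.05)
  expect_true(all(de$significant[truth$de_genes]))
  expect_equal(sign(de$log2FC[truth$de_genes]), truth$de_sign)
  # constant gene: identical class means -> log2FC exactly 0
  ds0 <- ds
  ds0$values[, 1] <- 5
  de0 <- label_based_de(ds0, ds0$labels)
  expect_equal(de0$log2FC[1], 0)
  expect_error(label_based_de(ds, rep(c("a", "b"), c(2, 198))), "fewer than 3")
})

test_that("sweep returns keyed metric groups over the grid", {
  ds <- tiny_ds(n_per_class = 20, d = 100, lfc = 3, seed = 22)
  cfg <- fast_config(learners = c("KNN-U", "XGB"))
  tab <- sweep_rp(ds, ks = c(10, 20), ms = 1, repeats = 1, folds = 3,
                  seed = 4, config = cfg)
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$k), c(10, 20))
  expect_error(sweep_rp(ds, ks = numeric(0), ms = 1), "empty")
})
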