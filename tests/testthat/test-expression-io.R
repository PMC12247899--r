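test_that("orientation contract holds for both layouts", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tsampA\tsampB", "g1\t1\t4", "g2\t2\t5", "g3\t3\t6"), tsv)
  ds <- read_expression(tsv, orientation = "genes")
  expect_equal(dim(ds), c(2L, 3L))
  expect_equal(ds$samples, c("sampA", "sampB"))
  expect_equal(ds$genes, c("g1", "g2", "g3"))
  expect_equal(unname(ds$values["sampB", "g3"]), 6)

  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tg1\tg2\tg3", "sampA\t1\t2\t3", "sampB\t4\t5\t6"), tsv2)
  ds2 <- read_expression(tsv2, orientation = "samples")
  expect_equal(ds$values, ds2$values)
})

test_that("incomplete or malformed files are rejected with diagnostics", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\t", "g2\t2\t3"), f)
  expect_error(read_expression(f), "ragged|empty")
  writeLines(c("gene\ts1\ts2", "g1\t1\tx", "g2\t2\t3"), f)
  expect_error(read_expression(f), "non-numeric")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g1\t2\t3"), f)
  expect_error(read_expression(f), "duplicate.*g1")
  writeLines(c("gene\ts1\ts2", "g1\t1\t2\t9", "g2\t2\t3"), f)
  expect_error(read_expression(f), "line 2")
})

test_that("write/read round trip reproduces values and bytes exactly", {
  ds <- tiny_ds(n_per_class = 4, d = 12)
  f1 <- tempfile(fileext = ".tsv")
  write_expression(ds, f1)
  back <- read_expression(f1, orientation = "genes")
  expect_equal(back$values, ds$values)
  f2 <- tempfile(fileext = ".tsv")
  write_expression(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("TPM conversion matches hand arithmetic and its identities", {
  counts <- expr_dataset(matrix(c(10, 20), 1, 2,
                                dimnames = list("s1", c("g1", "g2"))),
                         scale = "counts")
  tpm <- counts_to_tpm(counts, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm$values[1, ]), c(5e5, 5e5))
  expect_identical(tpm$scale, "tpm")

  eq <- expr_dataset(matrix(7, 2, 4), scale = "counts")
  expect_equal(unname(counts_to_tpm(eq, rep(100, 4))$values[1, ]), rep(2.5e5, 4))

  set.seed(1)
  cm <- matrix(rpois(60, 50), 5, 12)
  ds <- expr_dataset(cm, scale = "counts")
  lens <- runif(12, 200, 5000)
  out <- counts_to_tpm(ds, lens)
  expect_true(all(abs(rowSums(out$values) - 1e6) < 1e-3))
  # invariance to per-sample count rescaling
  cm2 <- cm * c(1, 10, 0.5, 3, 7)
  out2 <- counts_to_tpm(expr_dataset(cm2, scale = "counts"), lens)
  expect_equal(out$values, out2$values)
})

test_that("TPM conversion rejects bad lengths and all-zero samples", {
  ds <- expr_dataset(rbind(c(1, 2), c(0, 0)), samples = c("ok", "empty"),
                     genes = c("g1", "g2"), scale = "counts")
  expect_error(counts_to_tpm(ds, c(0, 100)), "positive")
  expect_error(counts_to_tpm(ds, c(100, 100)), "empty")
})

test_that("preprocessing matches hand arithmetic and guards leakage", {
  tr <- expr_dataset(rbind(c(3, 0), c(15, 0), c(63, 0)), scale = "tpm")
  pp <- preprocess(tr)
  # gene 1: log2(TPM+1) = 2,4,6 -> mean 4, sd 2
  expect_equal(unname(pp$values[, 1]), c(-1, 0, 1))
  # constant gene: centred, unscaled -> zeros
  expect_equal(unname(pp$values[, 2]), c(0, 0, 0))
  st <- attr(pp, "fit_stats")
  te <- expr_dataset(matrix(c(31, 7), 1, 2), genes = tr$genes, scale = "tpm")
  pte <- preprocess(te, st)
  expect_equal(unname(pte$values[1, 1]), (log2(32) - 4) / 2)
  # mutating held-out data must not change the applied statistics
  te2 <- te; te2$values[1, 1] <- 1e6
  expect_identical(attr(preprocess(te2, st), "fit_stats"), st)
  expect_error(preprocess(expr_dataset(matrix(1, 1, 3), scale = "tpm"), st),
               "gene set")
})
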