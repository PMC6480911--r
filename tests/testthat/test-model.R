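test_that("feature matrix column count is 259 + 4m + 8(m-1) on full blocks", {
  study <- small_study()
  m <- length(study$dataset$cells)
  fm <- build_matrix(study$dataset, study$genome, study$tracks,
                     names(study$dataset$cells)[1], "chr1")
  expect_equal(ncol(fm$x), 84 + 175 + 4 * m + 8 * (m - 1))
  expect_equal(anyDuplicated(colnames(fm$x)), 0L)
  # block order: sequence, structural, positional
  expect_true(all(grepl("^seq_", colnames(fm$x)[1:84])))
  expect_true(all(grepl("^str_", colnames(fm$x)[85:259])))
  expect_true(all(grepl("^pos_", colnames(fm$x)[260:ncol(fm$x)])))
  expect_true(all(fm$y %in% 0:1))
  expect_error(build_matrix(study$dataset, study$genome, study$tracks,
                            names(study$dataset$cells)[1], "chr99"),
               "empty partition")
})

test_that("single-cell matrix has 259 + 4 columns and positional block matches per-site calls", {
  study <- small_study()
  solo <- multicell_dataset(list(study$dataset$cells[[1]]))
  fm <- build_matrix(solo, study$genome, study$tracks,
                     names(solo$cells)[1], "chr1")
  expect_equal(ncol(fm$x), 263L)
  pos_block <- fm$x[, grepl("^pos_", colnames(fm$x)), drop = FALSE]
  for (i in sample(nrow(fm$x), 20)) {
    v <- positional_vector(solo, names(solo$cells)[1],
                           fm$keys$chrom[i], fm$keys$pos[i])
    expect_equal(unname(pos_block[i, ]), unname(v[1, ]))
  }
})

test_that("goss_select honours the size, ordering and weighting contracts", {
  g <- 1:10
  # keep everything
  all_cfg <- goss_config(a_frac = 1, b_frac = 0, seed = 1)
  res <- goss_select(g, all_cfg)
  expect_setequal(res$indices, 1:10)
  expect_equal(res$weights, rep(1, 10))

  # a=0.2, b=0.25 of the remainder: top {10, 9} plus 2 seeded draws
  res2 <- goss_select(g, goss_config(a_frac = 0.2, b_frac = 0.25, seed = 7))
  expect_equal(res2$indices[1:2], c(10L, 9L))
  expect_equal(length(res2$indices), 4L)
  expect_true(all(res2$indices[3:4] %in% 1:8))
  expect_equal(res2$weights, c(1, 1, 4, 4))   # inverse sampling fraction 8/2

  # a=0, b=1: uniform keep-all with unit weights
  res3 <- goss_select(g, goss_config(a_frac = 0, b_frac = 1, seed = 2))
  expect_setequal(res3$indices, 1:10)
  expect_equal(res3$weights, rep(1, 10))

  # b=0 with amplify: no sampled part, no division
  res4 <- goss_select(g, goss_config(a_frac = 0.3, b_frac = 0, seed = 2))
  expect_equal(length(res4$indices), 3L)
  expect_equal(res4$weights, rep(1, 3))
})

test_that("amplified GOSS preserves expected total gradient magnitude", {
  set.seed(41)
  g <- rexp(40)
  target <- sum(abs(g))
  est <- vapply(1:1000, function(s) {
    res <- goss_select(g, goss_config(a_frac = 0.2, b_frac = 0.3, seed = s))
    sum(abs(g[res$indices]) * res$weights)
  }, numeric(1))
  expect_lt(abs(mean(est) - target) / target, 0.02)
})

test_that("conflict weight counts co-nonzero rows", {
  x <- numeric(10); y <- numeric(10)
  x[c(1, 2, 3)] <- 1; y[c(4, 5)] <- 2
  expect_equal(efb_conflict(x, y), 0)           # disjoint supports
  y2 <- numeric(10); y2[c(3, 4)] <- 1
  expect_equal(efb_conflict(x, y2), 0.1)        # one shared row of ten
  expect_equal(efb_conflict(x, x), 0.3)         # identical support s/L
  expect_error(efb_conflict(x, y[1:5]), "length")
  expect_error(efb_conflict(numeric(0), numeric(0)), "empty")
})

test_that("bundling plan respects the conflict budget and is deterministic", {
  set.seed(42)
  x <- random_sparse_int(60, 12, density = 0.2)
  plan <- efb_bundle(x, d = 0.2)
  expect_setequal(unlist(plan$sets), 1:12)
  # exhaustive pair re-check within every set
  for (set in plan$sets) {
    if (length(set) < 2) next
    prs <- combn(set, 2)
    for (j in seq_len(ncol(prs)))
      expect_lte(efb_conflict(x[, prs[1, j]], x[, prs[2, j]]), 0.2)
  }
  expect_identical(plan$sets, efb_bundle(x, d = 0.2)$sets)

  # d = 0 with overlapping supports: every feature its own set
  xx <- cbind(a = c(1, 1, 0), b = c(1, 0, 1))
  expect_equal(lengths(efb_bundle(xx, d = 0)$sets), c(1L, 1L))

  # mutually exclusive one-hots collapse to one set for any d, including 0
  oh <- diag(4); colnames(oh) <- paste0("h", 1:4)
  expect_equal(length(efb_bundle(oh, d = 0)$sets), 1L)
  expect_equal(length(efb_bundle(oh, d = 0.5)$sets), 1L)
})

test_that("bundle merging uses offset encoding and inverts exactly", {
  # two exclusive binaries: merged values {0, 1, 2}, y = 1 maps to 2
  x <- cbind(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0))
  plan <- efb_bundle(x, d = 0.5)
  expect_equal(length(plan$sets), 1L)
  mg <- merge_bundles(x, plan)
  expect_setequal(unique(as.vector(mg$x)), c(0, 1, 2))
  expect_equal(unname(mg$x[3, 1]), 2)
  expect_equal(unmerge_bundles(mg)[, colnames(x)], x, ignore_attr = TRUE)

  # all-pairwise-conflicting columns at d = 0: every set is a singleton and
  # the matrix is unchanged up to column order
  x2 <- random_sparse_int(30, 5)
  x2[1, ] <- 1                     # one shared row makes every pair conflict
  plan2 <- efb_bundle(x2, d = 0)
  mg2 <- merge_bundles(x2, plan2)
  expect_equal(ncol(mg2$x), 5L)
  expect_equal(unmerge_bundles(mg2)[, colnames(x2)], x2, ignore_attr = TRUE)

  expect_error(merge_bundles(cbind(a = c(-1, 2)),
                             efb_bundle(cbind(a = c(-1, 2)), 0.1)),
               "non-negative integer")
})

test_that("merge_bundles is information-preserving for arbitrary plans", {
  set.seed(43)
  for (i in 1:5) {
    x <- random_sparse_int(50, 12, density = 0.25, max_val = 7)
    plan <- efb_bundle(x, d = 0.3)   # permits real conflicts
    mg <- merge_bundles(x, plan)
    expect_lte(ncol(mg$x), 12L)
    expect_equal(unmerge_bundles(mg)[, colnames(x)], x, ignore_attr = TRUE)
  }
})

test_that("training separates a separable toy problem and needs two classes", {
  set.seed(44)
  x1 <- rnorm(200)
  x1 <- x1[abs(x1) > 0.1]          # margin around the class boundary
  n <- length(x1)
  x <- cbind(f1 = x1, f2 = rnorm(n))
  y <- as.integer(x1 > 0)
  model <- train_model(list(x = x, y = y), model_config(n_trees = 50))
  pred <- predict(model, x)
  expect_equal(auc_roc(y, pred$prob), 1)
  expect_error(train_model(list(x = x, y = rep(1L, n)), model_config()),
               "single class")
})

test_that("prediction is invariant to column permutation via the manifest", {
  set.seed(45)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(x[, 1] > 0)
  model <- train_model(list(x = x, y = y), model_config(n_trees = 20))
  p1 <- predict(model, x)
  p2 <- predict(model, x[, c("c", "a", "b")])
  expect_equal(p1, p2)
  expect_error(predict(model, x[, c("a", "b")]), "lacks manifest")
})

test_that("training is reproducible under a fixed seed and single thread", {
  study <- small_study()
  fm <- build_matrix(study$dataset, NULL, NULL,
                     names(study$dataset$cells)[1], "chr1",
                     features = "pos")
  m1 <- train_model(fm, model_config(n_trees = 30, seed = 9, threads = 1))
  m2 <- train_model(fm, model_config(n_trees = 30, seed = 9, threads = 1))
  expect_identical(predict(m1, fm)$prob, predict(m2, fm)$prob)
  expect_identical(split_importance(m1), split_importance(m2))
})

test_that("held-out AUC beats a label-permuted control on correlated data", {
  study <- small_study()
  ds <- study$dataset
  cell <- names(ds$cells)[1]
  fm_tr <- build_matrix(ds, NULL, NULL, cell, "chr1", features = "pos")
  fm_te <- build_matrix(ds, NULL, NULL, cell, "chr2", features = "pos")
  model <- train_model(fm_tr, model_config(n_trees = 60, seed = 1))
  auc <- auc_roc(fm_te$y, predict(model, fm_te)$prob)
  set.seed(46)
  fm_perm <- list(x = fm_tr$x, y = sample(fm_tr$y))
  model0 <- train_model(fm_perm, model_config(n_trees = 60, seed = 1))
  auc0 <- auc_roc(fm_te$y, predict(model0, fm_te)$prob)
  expect_gt(auc, auc0 + 0.1)
})

test_that("importance aggregation sums split counts with stable ordering", {
  study <- small_study()
  fm <- build_matrix(study$dataset, NULL, NULL,
                     names(study$dataset$cells)[1], "chr1", features = "pos")
  m1 <- train_model(fm, model_config(n_trees = 20, seed = 1))
  m2 <- train_model(fm, model_config(n_trees = 20, seed = 2))
  # one model: aggregation is the identity on its own counts
  agg1 <- aggregate_importance(list(m1))
  imp1 <- split_importance(m1)
  expect_equal(setNames(agg1$splits, agg1$feature)[names(imp1)], imp1)
  # two models: element-wise sum, checked against a per-feature loop
  agg <- aggregate_importance(list(m1, m2))
  want <- split_importance(m1) + split_importance(m2)
  expect_equal(setNames(agg$splits, agg$feature)[names(want)], want)
  expect_true(all(diff(agg$splits) <= 0))
  # differing manifests refuse to aggregate
  m3 <- train_model(list(x = fm$x[, 1:4], y = fm$y),
                    model_config(n_trees = 5, seed = 1))
  expect_error(aggregate_importance(list(m1, m3)), "manifest")
})
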