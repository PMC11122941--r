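test_that("binary cross entropy matches closed forms", {
  expect_equal(bce(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce(c(0.9, 0.8, 0.2, 0.6), rep(1, 4)), 0.6122, tolerance = 1e-4)
  expect_lt(bce(c(rep(0.999, 5), rep(0.001, 5)), rep(1:0, each = 5)), 0.01)
  expect_message(bce(c(0, 1), c(0, 1)), "clamped")
})

test_that("the GFE loss matches the hand-evaluated example and its identities", {
  p <- c(0.9, 0.8, 0.2, 0.6); y <- rep(1, 4); mask <- c(1, 1, 0, 0)
  expect_equal(gfe(p, y, mask, gfe_context(accP = 0.8, accN = 0.9, W = 0.5)),
               0.6270, tolerance = 1e-4)
  b <- bce(p, y)
  # accP = 1, W = 0, accN = 0, or no observed positives: reduces to BCE
  expect_identical(gfe(p, y, mask, gfe_context(1, 0.9, 0.5)), b)
  expect_identical(gfe(p, y, mask, gfe_context(0.8, 0.9, 0)), b)
  expect_identical(gfe(p, y, mask, gfe_context(0.8, 0, 0.5)), b)
  expect_identical(gfe(p, y, rep(0, 4), gfe_context(0.8, 0.9, 0.5)), b)
  expect_identical(gfe(p, c(0, 0, 0, 0), mask, gfe_context(0.8, 0.9, 0.5)),
                   bce(p, c(0, 0, 0, 0)))
})

test_that("gfe >= bce for every batch (property over random cases)", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    p <- runif(n, 0.01, 0.99)
    y <- rbinom(n, 1, 0.5)
    mask <- rbinom(n, 1, 0.5)
    ctx <- gfe_context(runif(1), runif(1), runif(1))
    expect_gte(gfe(p, y, mask, ctx), bce_base <- bce(p, y) - 1e-12)
  }
})

test_that("context fields are validated", {
  expect_error(gfe_context(1.2, 0.5, 0.5))
  expect_error(gfe_context(0.5, -0.1, 0.5))
})

test_that("the MLP learns a separable toy and trains deterministically", {
  sep <- separable_set()
  m <- mlp_fit(sep$X, sep$y, loss = "bce", hidden = c(8, 4), lr = 0.01,
               epochs = 60, batch_size = 16, seed = 1)
  expect_gt(utils::tail(m$curves$acc_train, 1), 0.95)
  m2 <- mlp_fit(sep$X, sep$y, loss = "bce", hidden = c(8, 4), lr = 0.01,
                epochs = 60, batch_size = 16, seed = 1)
  expect_identical(m$curves, m2$curves)
})

test_that("pinning accP = 1 makes the GFE trajectory identical to BCE", {
  sep <- separable_set()
  args <- list(X = sep$X, y = sep$y, hidden = c(8, 4), lr = 0.01,
               epochs = 15, batch_size = 16, seed = 7)
  m_b <- do.call(mlp_fit, c(args, list(loss = "bce")))
  m_g <- do.call(mlp_fit, c(args, list(loss = "gfe",
                                       ctx = list(accP = 1, accN = 0.9))))
  expect_identical(m_b$curves$loss, m_g$curves$loss)
  expect_identical(m_b$curves$acc_train, m_g$curves$acc_train)
})

test_that("gfe training requires the discriminator context", {
  sep <- separable_set()
  expect_error(mlp_fit(sep$X, sep$y, loss = "gfe", epochs = 1),
               "requires")
})

test_that("the GFE correction term steers training toward observed positives", {
  # an exaggerated correction (accP = 0, accN = 1) must change the
  # trajectory relative to plain BCE when observed positives are present
  sep <- separable_set()
  mask <- as.integer(seq_along(sep$y) %% 2 == 0)
  args <- list(X = sep$X, y = sep$y, observed_mask = mask, hidden = c(8, 4),
               lr = 0.01, epochs = 10, batch_size = 16, seed = 7)
  m_b <- do.call(mlp_fit, c(args, list(loss = "bce")))
  m_g <- do.call(mlp_fit, c(args, list(loss = "gfe",
                                       ctx = list(accP = 0, accN = 1))))
  expect_false(identical(m_b$curves$loss, m_g$curves$loss))
  expect_true(all(m_g$curves$loss + 1e-12 >= 0))
})

test_that("evaluation reports confusion, per-class and balanced accuracy", {
  X <- matrix(0, 10, 2)
  y <- c(rep(1, 4), rep(0, 6))
  # TP=2, FN=2, TN=6, FP=0
  ev <- evaluate(stub_model(c(0.9, 0.8, 0.1, 0.2, rep(0.1, 6))), X, y)
  expect_equal(unname(ev$confusion), c(2, 0, 6, 2))
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$balanced_accuracy, 0.75)
  expect_equal(sum(ev$confusion), 10)

  perfect <- evaluate(stub_model(c(rep(0.9, 4), rep(0.1, 6))), X, y)
  expect_equal(perfect$balanced_accuracy, 1.0)

  # constant majority predictor: per-class {1, 0}, balanced 0.5
  const <- evaluate(stub_model(rep(0.1, 10)), X, y)
  expect_equal(unname(const$per_class), c(0, 1))
  expect_equal(const$balanced_accuracy, 0.5)

  # single-class set: absent-class accuracy undefined
  ev1 <- evaluate(stub_model(rep(0.9, 4)), X[1:4, ], rep(1, 4))
  expect_true(is.na(ev1$per_class["negative"]))
  expect_true(is.na(ev1$balanced_accuracy))
})

test_that("conventional baselines collapse on no-signal imbalance and learn separable data", {
  co <- no_signal_cohort(300, 20, 40, seed = 6)
  groups <- cluster_groups(minmax_apply(minmax_fit(co), co), k = 3, seed = 1)
  sp <- stratified_split(co, groups, seed = 1)
  tr <- cohort_subset(co, sp$train)
  va <- cohort_subset(co, sp$validation)
  rf <- train_baseline("random-forest", tr$X, tr$y, seed = 2)
  ev <- evaluate(rf, va$X, va$y)
  expect_equal(unname(ev$per_class["positive"]), 0)   # minority collapse

  sep <- separable_set()
  sv <- train_baseline("svm", sep$X, sep$y, seed = 1)
  expect_gt(evaluate(sv, sep$X, sep$y)$balanced_accuracy, 0.95)

  Xt <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  yt <- c(0, 0, 1, 1)  # axis-aligned, tree-learnable
  dt <- train_baseline("decision-tree", Xt[rep(1:4, 8), ], rep(yt, 8))
  expect_equal(mean(predict(dt, Xt, type = "class") == yt), 1.0)

  kn <- train_baseline("knn", sep$X, sep$y)
  expect_gt(evaluate(kn, sep$X, sep$y)$balanced_accuracy, 0.95)

  expect_error(train_baseline("boosting", sep$X, sep$y), "arg")
})
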