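test_that("default spec reproduces the study schema with exact class counts", {
  co <- default_cohort()
  expect_equal(ncol(co$X), 382)
  expect_equal(sum(co$y == 1), 78)
  expect_equal(sum(co$y == 0), 1376)
  expect_equal(as.vector(table(co$meta$kind)[c("clinical-continuous",
                                               "clinical-categorical",
                                               "metabolite")]),
               c(12, 7, 363))
  expect_false(anyDuplicated(co$ids) > 0)
  met <- co$meta$kind == "metabolite"
  expect_true(all(co$X[, met] > 0))
})

test_that("class counts are exact and output byte-identical across reruns", {
  spec <- cohort_spec(n_negative = 90, n_positive = 12, n_metabolites = 25,
                      seed = 31)
  for (s in c(2, 17, 99)) {
    co <- simulate_cohort(spec, seed = s)
    expect_equal(sum(co$y == 1), 12)
    expect_equal(sum(co$y == 0), 90)
  }
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1$X, co2$X)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(co1, f1); write_cohort(co2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_cohort(f1)
  expect_equal(back$X, co1$X, ignore_attr = TRUE)
  expect_identical(back$y, co1$y)
})

test_that("a spec with no signal leaves features unassociated with the label", {
  spec <- cohort_spec(n_negative = 400, n_positive = 400,
                      n_clinical_continuous = 0, n_clinical_categorical = 1,
                      categorical_level_counts = 2, n_metabolites = 0,
                      signal_features = data.frame(index = integer(),
                                                   beta = numeric()))
  # empirical odds ratio of the binary feature vs label across seeds
  ors <- vapply(1:20, function(s) {
    co <- simulate_cohort(spec, seed = 1000 + s)
    tab <- table(co$X[, 1], co$y) + 0.5
    (tab[2, 2] / tab[2, 1]) / (tab[1, 2] / tab[1, 1])
  }, numeric(1))
  expect_equal(mean(log(ors)), 0, tolerance = 0.1)
})

test_that("planted log-odds coefficients are recovered by a logistic refit", {
  # one binary feature with coefficient +2, large n: slopes are preserved
  # under exact-count (case-control style) sampling
  spec <- cohort_spec(n_negative = 16000, n_positive = 4000,
                      n_clinical_continuous = 2, n_clinical_categorical = 1,
                      categorical_level_counts = 2, n_metabolites = 0,
                      signal_features = data.frame(index = 3, beta = 2),
                      seed = 77)
  co <- simulate_cohort(spec)
  fit <- suppressWarnings(
    stats::glm(co$y ~ co$X[, 1] + co$X[, 2] + co$X[, 3], family = binomial()))
  expect_equal(unname(stats::coef(fit)[4]), 2, tolerance = 0.15)
})

test_that("signal feature indices are validated", {
  expect_error(cohort_spec(n_clinical_continuous = 1,
                           n_clinical_categorical = 0,
                           n_metabolites = 1,
                           signal_features = data.frame(index = 5, beta = 1)),
               "out of range")
  expect_error(cohort_spec(categorical_level_counts = rep(1, 7)), ">= 2")
})

test_that("MCAR injection hits designated columns and rows at stated rates", {
  spec0 <- cohort_spec(n_negative = 300, n_positive = 40, n_metabolites = 60,
                       seed = 8)
  co <- simulate_cohort(spec0)
  expect_identical(inject_missingness(co, spec0)$X, co$X)  # rates 0: unchanged

  spec_col <- cohort_spec(n_negative = 300, n_positive = 40, n_metabolites = 60,
                          missing_col_rate = 0.25, n_missing_cols = 30, seed = 8)
  cm <- inject_missingness(co, spec_col)
  met <- cm$meta$kind == "metabolite"
  frac <- colMeans(is.na(cm$X[, met, drop = FALSE]))
  hit <- frac[frac > 0]
  expect_length(hit, 30)
  # binomial error band around 0.25 at n = 340
  expect_true(all(abs(hit - 0.25) < 4 * sqrt(0.25 * 0.75 / 340)))
  expect_true(all(!is.na(cm$X[, !met])))  # clinical columns untouched

  spec_row <- cohort_spec(n_negative = 300, n_positive = 40, n_metabolites = 60,
                          missing_row_rate = 0.15, n_missing_rows = 10, seed = 8)
  rows <- 1:10
  cr <- inject_missingness(co, spec_row, rows = rows, seed = 21)
  rfrac <- rowMeans(is.na(cr$X[, met, drop = FALSE]))
  # designated rows should (typically) exceed the 10% participant filter
  expect_gte(sum(rfrac[rows] > 0.10), 8)
  expect_true(all(rfrac[-rows] == 0))
})

test_that("no-signal cohorts have null feature-label associations", {
  co <- no_signal_cohort(1376, 78, 382, seed = 4)
  expect_equal(sum(co$y == 1), 78)
  pvals <- apply(co$X, 2, function(v) stats::t.test(v ~ co$y)$p.value)
  expect_gte(mean(pvals > 0.05), 0.94)
  co2 <- no_signal_cohort(1376, 78, 382, seed = 4)
  expect_identical(co$X, co2$X)
  tiny <- no_signal_cohort(10, 10, 2, seed = 1)
  expect_equal(as.vector(table(tiny$y)), c(10, 10))
})
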