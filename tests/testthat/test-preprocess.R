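make_missing_cohort <- function() {
  # 20 records, 2 clinical + 4 metabolite features with planted missingness
  set.seed(11)
  X <- cbind(matrix(rnorm(40), 20, 2), matrix(exp(rnorm(80)), 20, 4))
  meta <- data.frame(
    name = c("c1", "c2", "m1", "m2", "m3", "m4"),
    kind = c(rep("clinical-continuous", 2), rep("metabolite", 4)),
    levels = NA_integer_)
  X[1:5, 3] <- NA     # m1: 25% missing -> removed at 0.20
  X[1:4, 4] <- NA     # m2: exactly 20% -> retained (strict inequality)
  new_cohort(X, rep(c(0, 1), 10), meta)
}

test_that("metabolite filter removes strictly-above-threshold columns only", {
  co <- make_missing_cohort()
  out <- filter_metabolites_by_missingness(co, 0.20)
  expect_false("m1" %in% out$meta$name)
  expect_true(all(c("m2", "m3", "m4") %in% out$meta$name))
  expect_true(all(c("c1", "c2") %in% out$meta$name))  # clinical never removed

  # a clinical column with heavy missingness is still never removed
  co$X[1:10, 1] <- NA
  out2 <- filter_metabolites_by_missingness(co, 0.20)
  expect_true("c1" %in% out2$meta$name)

  complete <- new_cohort(matrix(exp(rnorm(20)), 10, 2),
                         rep(0:1, 5),
                         data.frame(name = c("m1", "m2"), kind = "metabolite",
                                    levels = NA_integer_))
  expect_identical(filter_metabolites_by_missingness(complete)$X, complete$X)
})

test_that("participant filter removes strictly-above-threshold rows in lockstep", {
  co <- make_missing_cohort()
  # rows 1-4 miss m1+m2 = 2/4 = 50%; row 5 misses m1 only = 25%;
  # make a row at exactly 10%: impossible with 4 metabolites, so use 10
  set.seed(12)
  X <- matrix(exp(rnorm(200)), 20, 10)
  meta <- data.frame(name = sprintf("m%02d", 1:10), kind = "metabolite",
                     levels = NA_integer_)
  X[1:10, 1] <- NA          # rows 1-10 miss exactly 1/10 = 10% -> retained
  X[11:13, 1:2] <- NA       # rows 11-13 miss 20% -> removed
  co2 <- new_cohort(X, rep(0:1, 10), meta)
  out <- filter_participants_by_missingness(co2, 0.10)
  expect_equal(nrow(out$X), 17)
  expect_identical(out$y, co2$y[-(11:13)])
  expect_identical(out$ids, co2$ids[-(11:13)])
})

test_that("missingness filters commute with row and column permutations", {
  spec <- cohort_spec(n_negative = 60, n_positive = 15, n_metabolites = 40,
                      missing_col_rate = 0.3, n_missing_cols = 12,
                      missing_row_rate = 0.3, n_missing_rows = 8, seed = 3)
  co <- inject_missingness(simulate_cohort(spec), spec)
  run <- function(x) filter_participants_by_missingness(
    filter_metabolites_by_missingness(x))
  base <- run(co)
  set.seed(5)
  perm_rows <- sample(nrow(co$X))
  perm_cols <- sample(ncol(co$X))
  co_p <- structure(list(ids = co$ids[perm_rows],
                         X = co$X[perm_rows, perm_cols],
                         y = co$y[perm_rows],
                         meta = co$meta[perm_cols, ]), class = "cohort")
  out_p <- run(co_p)
  expect_setequal(out_p$ids, base$ids)
  expect_setequal(out_p$meta$name, base$meta$name)
})

test_that("log transform hits metabolites only and flags non-positive values", {
  X <- cbind(c(-1, 2, 3), exp(c(1, 0, 2)))
  meta <- data.frame(name = c("clin", "met"),
                     kind = c("clinical-continuous", "metabolite"),
                     levels = NA_integer_)
  co <- new_cohort(X, c(0, 1, 0), meta)
  out <- log_transform_metabolites(co)
  expect_equal(out$X[, "met"], c(1, 0, 2), ignore_attr = TRUE)
  expect_equal(out$X[, "clin"], X[, 1], ignore_attr = TRUE)  # clinical unchanged

  co$X[2, 2] <- NA  # missing stays missing
  out2 <- log_transform_metabolites(co)
  expect_true(is.na(out2$X[2, 2]))

  bad <- co; bad$X[1, 2] <- 0   # bypass constructor to plant the bad value
  expect_error(log_transform_metabolites(bad), "non-positive metabolite")
})

test_that("log transform symmetrizes a log-normal column", {
  set.seed(21)
  n <- 4000
  X <- matrix(exp(rnorm(n)), ncol = 1)
  co <- new_cohort(X, rep(0:1, n / 2),
                   data.frame(name = "m", kind = "metabolite",
                              levels = NA_integer_))
  v <- log_transform_metabolites(co)$X[, 1]
  skew <- mean((v - mean(v))^3) / stats::sd(v)^3
  expect_lt(abs(skew), 0.15)
})

test_that("chained imputation recovers linear structure and beats mean fill", {
  # identity on complete data
  co <- make_missing_cohort()
  complete <- filter_participants_by_missingness(
    filter_metabolites_by_missingness(co), 0)
  expect_identical(impute_chained(complete)$X, complete$X)

  # two perfectly correlated columns: exact recovery
  v <- rnorm(15)
  X <- cbind(v, v, rnorm(15))
  X[4, 1] <- NA
  co2 <- new_cohort(X, rep(c(0, 1, 0), 5),
                    data.frame(name = c("a", "b", "c"),
                               kind = "clinical-continuous",
                               levels = NA_integer_))
  out <- impute_chained(co2)
  expect_equal(out$X[4, 1], v[4], tolerance = 1e-6, ignore_attr = TRUE)

  # correlated multivariate normal, 10% MCAR: beat the mean-fill oracle
  skip_if_not_installed("MASS")
  set.seed(33)
  S <- 0.7 + diag(0.3, 6)
  Z <- MASS::mvrnorm(300, mu = rep(0, 6), Sigma = S)
  mask <- matrix(runif(length(Z)) < 0.10, nrow(Z))
  mask[, 1] <- FALSE  # keep one fully observed feature
  Zm <- Z; Zm[mask] <- NA
  co3 <- new_cohort(Zm, rep(0:1, 150),
                    data.frame(name = sprintf("f%d", 1:6),
                               kind = "clinical-continuous",
                               levels = NA_integer_))
  imp <- impute_chained(co3)$X
  meanfill <- apply(Zm, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE); col
  })
  rmse <- function(M) sqrt(mean((M[mask] - Z[mask])^2))
  expect_lt(rmse(imp), rmse(meanfill))

  all_na <- co2; all_na$X[, 2] <- NA
  expect_error(impute_chained(all_na), "zero observed")
})

test_that("min-max scaling maps, clips, degenerates and round-trips as specified", {
  sc <- minmax_fit(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(as.vector(minmax_apply(sc, matrix(c(2, 4, 6), ncol = 1))),
               c(0, 0.5, 1))
  expect_equal(as.vector(minmax_apply(sc, matrix(8, 1, 1))), 1)   # clipped
  expect_equal(as.vector(minmax_apply(sc, matrix(0, 1, 1))), 0)

  const <- minmax_fit(matrix(rep(3, 5), ncol = 1))
  expect_equal(as.vector(minmax_apply(const, matrix(rep(3, 5), ncol = 1))),
               rep(0, 5))

  set.seed(6)
  M <- matrix(rnorm(60), 20, 3)
  sc2 <- minmax_fit(M)
  S <- minmax_apply(sc2, M)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(minmax_invert(sc2, S), M, tolerance = 1e-9, ignore_attr = TRUE)

  # values outside the fitted range land in [0,1] too
  S_out <- minmax_apply(sc2, M * 3)
  expect_true(all(S_out >= 0 & S_out <= 1))

  expect_error(minmax_apply(sc2, M[, 1:2]), "mismatch")

  f <- tempfile(fileext = ".json")
  colnames(M) <- c("a", "b", "c")
  sc3 <- minmax_fit(M)
  write_scaler(sc3, f)
  back <- read_scaler(f)
  expect_equal(back$min, sc3$min, ignore_attr = TRUE)
  expect_equal(back$max, sc3$max, ignore_attr = TRUE)
})
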