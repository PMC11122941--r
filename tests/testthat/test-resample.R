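# Independent brute-force oracles (plain loops, no shared code with the
# implementation) back the small-instance equivalence checks.

brute_enn <- function(X, y, k) {
  n <- nrow(X)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    keep[i] <- mean(y[nb] == y[i]) >= 0.5
  }
  which(keep)
}

# is `pt` on the segment between minority record i and one of its k nearest
# minority neighbours?
on_some_smote_segment <- function(pt, pool, kk) {
  m <- nrow(pool)
  for (i in seq_len(m)) {
    d <- sqrt(colSums((t(pool) - pool[i, ])^2))
    d[i] <- Inf
    for (j in order(d)[seq_len(min(kk, m - 1))]) {
      v <- pool[j, ] - pool[i, ]
      w <- pt - pool[i, ]
      lam <- if (sum(v^2) == 0) 0 else sum(w * v) / sum(v^2)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((w - lam * v)^2)) < 1e-8) return(TRUE)
    }
  }
  FALSE
}

test_that("smote points lie on minority segments (two-point convexity case)", {
  syn <- smote(rbind(c(0, 0), c(1, 1)), 50, k = 1, seed = 3)
  expect_equal(nrow(syn), 50)
  expect_true(all(abs(syn[, 1] - syn[, 2]) < 1e-12))
  expect_true(all(syn >= -1e-12 & syn <= 1 + 1e-12))
  expect_equal(nrow(smote(rbind(c(0, 0), c(1, 1)), 0, k = 1)), 0)
})

test_that("smote agrees with the segment oracle and stays in the convex hull", {
  set.seed(25)
  for (trial in 1:5) {
    M <- matrix(runif(2 * sample(6:15, 1)), ncol = 2)
    syn <- smote(M, 30, k = 3, seed = trial)
    ok <- apply(syn, 1, function(r) on_some_smote_segment(r, M, 3))
    expect_true(all(ok))
    # convex hull membership via bounding of each coordinate by construction
    expect_true(all(syn[, 1] >= min(M[, 1]) - 1e-12 &
                    syn[, 1] <= max(M[, 1]) + 1e-12))
  }
})

test_that("smote lowers k with a warning when the minority is tiny", {
  M <- matrix(runif(8), 4, 2)
  expect_warning(syn <- smote(M, 10, k = 5, seed = 1), "lowering k")
  expect_equal(nrow(syn), 10)
  expect_warning(one <- smote(M[1, , drop = FALSE], 3, k = 5, seed = 1),
                 "single minority")
  expect_true(all(one[1, ] == M[1, ]))
})

test_that("enn removes majority-vote disagreements, simultaneously", {
  # one B point inside a tight A cluster is removed
  set.seed(8)
  X <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2), c(0, 0))
  y <- c(rep(0, 10), 1)
  kept <- enn(X, y, k = 3)
  expect_false(11 %in% kept)
  expect_true(all(kept %in% 1:10))

  # single class: nothing removed
  expect_equal(enn(X, rep(1, 11), k = 3), 1:11)

  # two far-separated pure clusters: nothing removed, idempotent
  X2 <- rbind(matrix(rnorm(16, sd = 0.1), 8, 2),
              matrix(rnorm(16, mean = 50, sd = 0.1), 8, 2))
  y2 <- rep(c(0, 1), each = 8)
  k1 <- enn(X2, y2, k = 3)
  expect_equal(k1, 1:16)
  expect_equal(enn(X2[k1, ], y2[k1], k = 3), seq_along(k1))
})

test_that("enn matches the brute-force oracle on random small instances", {
  set.seed(26)
  for (trial in 1:8) {
    n <- sample(10:50, 1)
    X <- matrix(rnorm(2 * n), n, 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    expect_equal(enn(X, y, k = 3), brute_enn(X, y, 3))
  }
})

test_that("iterative balancing terminates at the majority target with full provenance", {
  set.seed(27)
  obs <- matrix(runif(240 * 4), 240, 4)
  y <- c(rep(0, 200), rep(1, 40))
  gen <- matrix(runif(300 * 4), 300, 4)
  bal <- iterative_balance(obs, y, gen, batch = 50, target_majority = 150,
                           repeats = 1, seed = 3)
  expect_lte(max(table(bal$y)), 1000)
  expect_true(all(bal$provenance %in%
                  c("observed", "gan-generated", "smote-synthetic")))
  expect_equal(length(bal$y), nrow(bal$X))
  expect_gte(nrow(bal$log), 1)
  # deterministic under the seed
  bal2 <- iterative_balance(obs, y, gen, batch = 50, target_majority = 150,
                            repeats = 1, seed = 3)
  expect_identical(bal$log, bal2$log)
  expect_identical(bal$X, bal2$X)
})

test_that("a target at or above the initial majority yields a noted single pass", {
  set.seed(28)
  obs <- matrix(runif(120 * 3), 120, 3)
  y <- c(rep(0, 100), rep(1, 20))
  gen <- matrix(runif(400 * 3), 400, 3)
  bal <- iterative_balance(obs, y, gen, batch = 100, target_majority = 1000,
                           repeats = 1, seed = 2)
  expect_match(bal$note, "single pass")
  expect_lte(max(table(bal$y)), 1000)
})

test_that("zero pending records gives a single smote+enn pass; repeats = 0 appends", {
  set.seed(29)
  obs <- matrix(runif(60 * 3), 60, 3)
  y <- c(rep(0, 45), rep(1, 15))
  none <- matrix(numeric(), 0, 3)
  bal <- iterative_balance(obs, y, none, repeats = 1, target_majority = 40,
                           seed = 1)
  expect_equal(nrow(bal$log), 1)
  expect_equal(sum(bal$log$added), 0)

  gen <- matrix(runif(30 * 3), 30, 3)
  raw <- iterative_balance(obs, y, gen, repeats = 0, seed = 1)
  expect_equal(length(raw$y), 90)
  expect_equal(sum(raw$provenance == "gan-generated"), 30)
  expect_equal(nrow(raw$log), 0)
})

test_that("two-pass balancing consumes pending records in the first pass only", {
  set.seed(30)
  obs <- matrix(runif(100 * 3), 100, 3)
  y <- c(rep(0, 80), rep(1, 20))
  gen <- matrix(runif(120 * 3), 120, 3)
  bal <- iterative_balance(obs, y, gen, batch = 60, target_majority = 60,
                           repeats = 2, seed = 4)
  expect_lte(sum(bal$log$added), 120)
  expect_equal(max(bal$log$pass), 2)
  expect_equal(sum(bal$log$added[bal$log$pass == 2]), 0)
})
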