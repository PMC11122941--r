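# From-scratch SMOTE and edited-nearest-neighbour cleaning, plus the
# iterative balancing schedule that feeds pending generated positives into
# the training pool in chunks of 100, equalizes the classes by SMOTE, and
# prunes noisy and borderline records by ENN until the majority count
# reaches its target or the pending queue is exhausted.

#' Synthetic minority oversampling (SMOTE)
#'
#' Each synthetic record is `x + lambda * (x_nn - x)` with `x` a sampled
#' minority record, `x_nn` one of its `k` nearest minority neighbours
#' (Euclidean), and `lambda ~ Uniform(0, 1)`, so every synthetic point lies
#' on a segment between two minority records (hence inside the minority
#' convex hull).
#'
#' @param minority matrix of minority-class records.
#' @param n_new number of synthetic records to produce.
#' @param k neighbourhood size, default 5. When the minority count is
#'   `<= k`, `k` is lowered to `count - 1` with a warning.
#' @param seed RNG seed.
#' @return an `n_new x p` matrix (0 rows when `n_new = 0`).
#' @export
smote <- function(minority, n_new, k = 5, seed = 1L) {
  M <- as.matrix(minority)
  m <- nrow(M)
  if (n_new == 0) return(M[integer(), , drop = FALSE])
  if (m < 1) stop("no minority records to oversample")
  if (m == 1) {
    warning("single minority record: synthetic records are copies of it")
    return(M[rep(1, n_new), , drop = FALSE])
  }
  if (m <= k) {
    warning(sprintf("minority count %d <= k = %d; lowering k to %d", m, k, m - 1))
    k <- m - 1
  }
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  nnm <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1) matrix(nnm, ncol = 1) else t(nnm)
  with_seed(seed, {
    base <- sample.int(m, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
    lam <- stats::runif(n_new)
    M[base, , drop = FALSE] + lam * (M[pick, , drop = FALSE] - M[base, , drop = FALSE])
  })
}

#' Edited nearest neighbours (ENN)
#'
#' A record is removed when the majority vote of its `k` nearest neighbours
#' (excluding itself) disagrees with its own label. Votes are computed on
#' the original set and deletions applied simultaneously, so the output is
#' a subset of the input and single-class sets pass through unchanged.
#'
#' @param records matrix of records.
#' @param labels binary labels.
#' @param k neighbourhood size, default 3.
#' @return integer indices of the retained records.
#' @export
enn <- function(records, labels, k = 3) {
  X <- as.matrix(records)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  if (n <= k) return(seq_len(n))
  if (length(unique(labels)) < 2) return(seq_len(n))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  keep <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    vote <- mean(labels[nb] == labels[i])
    vote >= 0.5  # strict-majority disagreement triggers removal
  }, logical(1))
  which(keep)
}

#' Iterative SMOTE + ENN balancing of the combined training pool
#'
#' Starting from the observed training records, each iteration (i) moves
#' the next `batch` pending generated positives into the pool, (ii) applies
#' [smote()] to equalize the class counts, and (iii) applies [enn()]
#' cleaning, stopping at the first iteration where the majority-class count
#' is `<= target_majority` or the pending queue is exhausted. The whole
#' procedure can be repeated (`repeats`, default 2, the two-pass
#' configuration); `repeats = 0` simply appends all pending records.
#' Provenance (`observed` / `gan-generated` / `smote-synthetic`) is carried
#' through all deletions, and a per-iteration log of class counts is
#' returned. When the target is already at or above the initial majority
#' count the loop degenerates to a single pass, noted in the log.
#'
#' @param observed matrix of observed training records.
#' @param labels their binary labels.
#' @param generated matrix of pending generated positive records (label 1).
#' @param batch pending records moved in per iteration, default 100.
#' @param target_majority stopping target for the majority-class count,
#'   default 1000.
#' @param repeats how many times the full schedule is applied, in 0..2+.
#' @param k_smote,k_enn neighbourhood sizes.
#' @param seed RNG seed.
#' @return an object of class `balanced_set` with `X`, `y`, `provenance`,
#'   an iteration `log` data.frame, and `note`.
#' @export
iterative_balance <- function(observed, labels, generated,
                              batch = 100, target_majority = 1000,
                              repeats = 2, k_smote = 5, k_enn = 3,
                              seed = 1L) {
  X <- as.matrix(observed)
  y <- as.integer(labels)
  generated <- as.matrix(generated)
  stopifnot(length(y) == nrow(X))
  prov <- rep("observed", nrow(X))
  note <- character()
  maj_count <- function(yy) max(table(factor(yy, levels = c(0, 1))))
  if (repeats == 0) {
    X <- rbind(X, generated)
    y <- c(y, rep(1L, nrow(generated)))
    prov <- c(prov, rep("gan-generated", nrow(generated)))
    return(structure(list(X = X, y = y, provenance = prov,
                          log = data.frame(), note = "repeats = 0: pending appended, no resampling"),
                     class = "balanced_set"))
  }
  if (target_majority >= maj_count(y))
    note <- c(note, sprintf(
      "target_majority (%d) >= initial majority count (%d): single pass",
      target_majority, maj_count(y)))
  log <- list()
  it <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      pending <- if (r == 1) generated else generated[integer(), , drop = FALSE]
      repeat {
        it <- it + 1L
        n_add <- min(batch, nrow(pending))
        if (n_add > 0) {
          X <- rbind(X, pending[seq_len(n_add), , drop = FALSE])
          y <- c(y, rep(1L, n_add))
          prov <- c(prov, rep("gan-generated", n_add))
          pending <- pending[-seq_len(n_add), , drop = FALSE]
        }
        tab <- table(factor(y, levels = c(0, 1)))
        minor_lab <- as.integer(names(tab)[which.min(tab)])
        n_smote <- as.integer(max(tab) - min(tab))
        if (n_smote > 0 && min(tab) > 0) {
          synth <- smote(X[y == minor_lab, , drop = FALSE], n_smote,
                         k = k_smote,
                         seed = sample.int(.Machine$integer.max, 1))
          X <- rbind(X, synth)
          y <- c(y, rep(minor_lab, n_smote))
          prov <- c(prov, rep("smote-synthetic", n_smote))
        }
        kept <- enn(X, y, k = k_enn)
        n_removed <- nrow(X) - length(kept)
        X <- X[kept, , drop = FALSE]
        y <- y[kept]
        prov <- prov[kept]
        log[[it]] <- data.frame(
          pass = r, iteration = it, added = n_add, smote_added = n_smote,
          enn_removed = n_removed,
          n_negative = sum(y == 0), n_positive = sum(y == 1))
        if (maj_count(y) <= target_majority || nrow(pending) == 0) break
      }
    }
  })
  structure(list(X = X, y = y, provenance = prov,
                 log = do.call(rbind, log),
                 note = if (length(note)) paste(note, collapse = "; ") else NULL),
            class = "balanced_set")
}

#' @export
print.balanced_set <- function(x, ...) {
  tab <- table(factor(x$y, levels = c(0, 1)))
  pv <- table(x$provenance)
  cat(sprintf("<balanced_set> %d records (%d negative / %d positive), %d iterations\n",
              length(x$y), tab["0"], tab["1"],
              if (is.null(x$log) || nrow(x$log) == 0) 0L else nrow(x$log)))
  cat("  provenance:", paste(sprintf("%s=%d", names(pv), pv), collapse = ", "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
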