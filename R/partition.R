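# Grouped train/test/validation partitioning: records are first clustered
# on the normalized feature matrix, then each cluster is split 64/16/20 and
# the per-cluster partitions merged, so all three partitions cover every
# region of feature space.

#' Cluster records into feature-space groups
#'
#' Centroid-based (k-means) clustering of the normalized feature matrix
#' into `k` groups, the grouping used to stratify the train/test/validation
#' split. Deterministic given the seed.
#'
#' @param cohort a complete `cohort` or numeric matrix (normalized).
#' @param k number of groups, default 3.
#' @param seed RNG seed.
#' @return integer vector of group labels in `1..k`.
#' @export
cluster_groups <- function(cohort, k = 3, seed = 1L) {
  X <- if (inherits(cohort, "cohort")) cohort$X else as.matrix(cohort)
  if (k > nrow(X)) stop("k must not exceed the number of records")
  if (k == 1) return(rep(1L, nrow(X)))
  with_seed(seed, {
    km <- stats::kmeans(X, centers = k, nstart = 5, iter.max = 100)
    as.integer(km$cluster)
  })
}

# Largest-remainder allocation of n records to fractions.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw + 1e-9)
  rem <- raw - base
  leftover <- n - sum(base)
  if (leftover > 0) {
    extra <- order(-rem, seq_along(fractions))[seq_len(leftover)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Grouped stratified split
#'
#' Within each group the records are shuffled by the seed and allocated to
#' train/test/validation by largest-remainder rounding of the requested
#' fractions; the per-group partitions are then merged.
#'
#' @param cohort a `cohort` (its ids are split) or a character vector of ids.
#' @param groups integer group label per record.
#' @param fractions train/test/validation fractions summing to 1.
#' @param seed RNG seed.
#' @return an object of class `split_indices` with fields `train`, `test`,
#'   `validation` (disjoint, exhaustive id sets) and `groups`.
#' @export
stratified_split <- function(cohort, groups, fractions = c(0.64, 0.16, 0.20),
                             seed = 1L) {
  ids <- if (inherits(cohort, "cohort")) cohort$ids else as.character(cohort)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three values summing to 1")
  if (length(groups) != length(ids)) stop("one group label per record required")
  parts <- list(train = character(), test = character(), validation = character())
  with_seed(seed, {
    for (g in sort(unique(groups))) {
      gid <- ids[groups == g]
      gid <- gid[sample.int(length(gid))]
      counts <- largest_remainder(length(gid), fractions)
      cuts <- cumsum(counts)
      parts$train <- c(parts$train, gid[seq_len(counts[1])])
      if (counts[2] > 0)
        parts$test <- c(parts$test, gid[(cuts[1] + 1):cuts[2]])
      if (counts[3] > 0)
        parts$validation <- c(parts$validation, gid[(cuts[2] + 1):cuts[3]])
    }
  })
  structure(list(train = parts$train, test = parts$test,
                 validation = parts$validation,
                 groups = stats::setNames(as.integer(groups), ids)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  n <- length(x$train) + length(x$test) + length(x$validation)
  cat(sprintf("<split_indices> %d records: train %d / test %d / validation %d\n",
              n, length(x$train), length(x$test), length(x$validation)))
  invisible(x)
}

#' Serialize / load a split as JSON
#'
#' @param split a `split_indices`.
#' @param path JSON path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(list(train = split$train, test = split$test,
                            validation = split$validation,
                            groups = as.list(split$groups)),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = obj$train, test = obj$test,
                 validation = obj$validation,
                 groups = unlist(obj$groups)),
            class = "split_indices")
}
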