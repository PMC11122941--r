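# Data-cleaning chain for the participant-by-feature table: metabolite and
# participant missingness filters, natural-log transform of the metabolite
# panel, deterministic chained-equation imputation, and min-max scaling
# fitted on a designated partition.

#' Drop metabolite columns with excessive missingness
#'
#' Removes every metabolite column whose missing fraction is strictly
#' greater than `threshold` (a column with exactly the threshold fraction is
#' retained). Clinical columns are never removed.
#'
#' @param cohort a `cohort`.
#' @param threshold missing-fraction cutoff, default 0.20.
#' @return the filtered `cohort` with metadata updated.
#' @export
filter_metabolites_by_missingness <- function(cohort, threshold = 0.20) {
  stopifnot(threshold >= 0, threshold <= 1)
  frac <- colMeans(is.na(cohort$X))
  drop <- cohort$meta$kind == "metabolite" & frac > threshold
  if (any(drop)) {
    cohort$X <- cohort$X[, !drop, drop = FALSE]
    cohort$meta <- cohort$meta[!drop, , drop = FALSE]
    rownames(cohort$meta) <- NULL
  }
  cohort
}

#' Drop participants with excessive metabolite missingness
#'
#' Removes every record whose missing fraction over the metabolite columns
#' is strictly greater than `threshold` (exactly the threshold is
#' retained). Labels and ids are filtered in lockstep.
#'
#' @param cohort a `cohort`.
#' @param threshold missing-fraction cutoff, default 0.10.
#' @return the filtered `cohort`.
#' @export
filter_participants_by_missingness <- function(cohort, threshold = 0.10) {
  stopifnot(threshold >= 0, threshold <= 1)
  met <- cohort$meta$kind == "metabolite"
  if (!any(met)) return(cohort)
  frac <- rowMeans(is.na(cohort$X[, met, drop = FALSE]))
  keep <- frac <= threshold
  cohort_subset(cohort, which(keep))
}

#' Natural-log transform of the metabolite columns
#'
#' Metabolite panels are right-skewed on the raw scale; the natural log is
#' applied to metabolite columns only. Missing cells stay missing; a
#' non-positive observed metabolite value is a data error reported with its
#' row and column.
#'
#' @param cohort a `cohort`.
#' @return the transformed `cohort`.
#' @export
log_transform_metabolites <- function(cohort) {
  met <- which(cohort$meta$kind == "metabolite")
  for (j in met) {
    v <- cohort$X[, j]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0)
      stop(sprintf("non-positive metabolite value at record '%s', feature '%s'",
                   cohort$ids[bad[1]], cohort$meta$name[j]))
    cohort$X[, j] <- log(v)
  }
  cohort
}

#' Chained-equation imputation
#'
#' Completes the feature matrix by iterative regression: missing cells are
#' initialized at their column means, then each incomplete feature is
#' regressed (ordinary least squares on its originally observed rows) on all
#' other features and its missing cells replaced by the fitted values,
#' sweeping over the incomplete features `n_sweeps` times. A single
#' deterministic completion is returned (no posterior draws), so the result
#' depends only on the data.
#'
#' @param cohort a `cohort` (apply after the two missingness filters).
#' @param n_sweeps number of full passes over the incomplete features.
#' @param seed kept for interface stability; the completion is
#'   deterministic.
#' @return the completed `cohort` (no `NA` cells).
#' @export
impute_chained <- function(cohort, n_sweeps = 10, seed = NULL) {
  X <- cohort$X
  obs_count <- colSums(!is.na(X))
  if (any(obs_count == 0))
    stop("feature with zero observed values: ",
         cohort$meta$name[which(obs_count == 0)[1]])
  if (!any(obs_count == nrow(X)))
    stop("chained imputation requires at least one fully observed feature")
  miss_cols <- which(colSums(is.na(X)) > 0)
  if (length(miss_cols) == 0) return(cohort)
  miss_idx <- lapply(miss_cols, function(j) which(is.na(X[, j])))
  # mean initialization
  Xc <- X
  for (k in seq_along(miss_cols)) {
    j <- miss_cols[k]
    Xc[miss_idx[[k]], j] <- mean(X[, j], na.rm = TRUE)
  }
  for (s in seq_len(n_sweeps)) {
    for (k in seq_along(miss_cols)) {
      j <- miss_cols[k]
      rows_obs <- which(!is.na(X[, j]))
      A <- cbind(1, Xc[rows_obs, -j, drop = FALSE])
      qr_A <- qr(A)
      beta <- qr.coef(qr_A, X[rows_obs, j])
      beta[is.na(beta)] <- 0  # aliased columns contribute nothing
      pred <- cbind(1, Xc[miss_idx[[k]], -j, drop = FALSE]) %*% beta
      Xc[miss_idx[[k]], j] <- pred
    }
  }
  cohort$X <- Xc
  cohort
}

#' Fit a per-feature min-max scaler
#'
#' Learns per-feature minimum and maximum from a fitting partition
#' (typically the training records only, so no information leaks from the
#' evaluation partitions into the scaling constants).
#'
#' @param cohort a complete `cohort` (or numeric matrix) to fit on.
#' @return an object of class `minmax_scaler`.
#' @export
minmax_fit <- function(cohort) {
  X <- if (inherits(cohort, "cohort")) cohort$X else as.matrix(cohort)
  if (nrow(X) == 0) stop("cannot fit a scaler on an empty partition")
  structure(list(min = apply(X, 2, min, na.rm = TRUE),
                 max = apply(X, 2, max, na.rm = TRUE),
                 features = colnames(X)),
            class = "minmax_scaler")
}

#' @export
print.minmax_scaler <- function(x, ...) {
  cat(sprintf("<minmax_scaler> %d features; %d constant\n",
              length(x$min), sum(x$max == x$min)))
  invisible(x)
}

#' Apply a fitted min-max scaler
#'
#' Maps each value to `(v - min) / (max - min)`. A constant feature maps to
#' 0, and values outside the fitted range are clipped into `[0, 1]`.
#'
#' @param scaler a `minmax_scaler`.
#' @param cohort a `cohort` or numeric matrix with the scaler's features.
#' @return the scaled object, same type as the input.
#' @export
minmax_apply <- function(scaler, cohort) {
  is_cohort <- inherits(cohort, "cohort")
  X <- if (is_cohort) cohort$X else as.matrix(cohort)
  if (ncol(X) != length(scaler$min) ||
      (!is.null(colnames(X)) && !is.null(scaler$features) &&
       !identical(colnames(X), scaler$features)))
    stop("scaler/cohort feature mismatch")
  rng <- scaler$max - scaler$min
  const <- rng == 0
  rng[const] <- 1
  S <- add_row(X, -scaler$min) / matrix(rng, nrow(X), ncol(X), byrow = TRUE)
  S[, const] <- 0
  S <- pmin(pmax(S, 0), 1)
  if (is_cohort) { cohort$X <- S; cohort } else S
}

#' Invert a min-max scaling
#'
#' Maps scaled values back to the original scale; exact for values that were
#' inside the fitted range (clipped values cannot be recovered). Constant
#' features map back to their constant.
#'
#' @param scaler a `minmax_scaler`.
#' @param X scaled numeric matrix.
#' @return matrix on the original scale.
#' @export
minmax_invert <- function(scaler, X) {
  X <- as.matrix(X)
  rng <- scaler$max - scaler$min
  add_row(X * matrix(rng, nrow(X), ncol(X), byrow = TRUE), scaler$min)
}

#' Serialize / load a min-max scaler as JSON
#'
#' @param scaler a `minmax_scaler`.
#' @param path JSON path.
#' @return `path` (write) or the scaler (read).
#' @export
write_scaler <- function(scaler, path) {
  obj <- stats::setNames(
    lapply(seq_along(scaler$min), function(j) c(scaler$min[j], scaler$max[j])),
    scaler$features %||% sprintf("f%d", seq_along(scaler$min)))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = vapply(obj, `[`, numeric(1), 1),
                 max = vapply(obj, `[`, numeric(1), 2),
                 features = names(obj)),
            class = "minmax_scaler")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
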