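# Mean-replacement sensitivity analysis: for each feature in turn, the
# positive records have that column overwritten by the non-case mean and
# the trained model is re-run; the mean absolute change in predicted score
# measures the feature's influence. Averaging across replicate pipelines
# and ranking yields the feature-importance report.

#' Per-feature means over the negative (non-case) records
#'
#' @param cohort a `cohort`, or a list/matrix pair: when `y` is supplied,
#'   `cohort` may be a plain feature matrix.
#' @param y binary labels when `cohort` is a matrix.
#' @return named vector of per-feature means over `y == 0` records, on
#'   whatever scale the input is on (use the post-preprocessing scale the
#'   model was trained on).
#' @export
nonmi_feature_means <- function(cohort, y = NULL) {
  if (inherits(cohort, "cohort")) { X <- cohort$X; y <- cohort$y }
  else X <- as.matrix(cohort)
  if (sum(y == 0) < 1) stop("at least one negative record required")
  colMeans(X[y == 0, , drop = FALSE])
}

#' Mean-replacement sensitivity of each feature
#'
#' For each feature `j`: copy the positive records, overwrite column `j`
#' with the negative-class mean (all other columns untouched), re-run the
#' model, and record the mean absolute change in predicted score. A
#' feature the model provably ignores changes nothing and scores exactly 0.
#'
#' @param model a trained classifier with a `predict(model, X,
#'   type = "response")` method.
#' @param positive_records matrix of positive records on the model's input
#'   scale (nonempty).
#' @param means named per-feature replacement means, e.g. from
#'   [nonmi_feature_means()]. Categorical features are replaced by the mean
#'   of their integer codes, consistent with a model trained on the codes.
#' @return named vector of per-feature mean absolute prediction changes.
#' @export
mean_replacement_sensitivity <- function(model, positive_records, means) {
  X <- as.matrix(positive_records)
  if (nrow(X) == 0) stop("no positive records supplied")
  if (length(means) != ncol(X))
    stop("replacement means do not match the model's feature schema")
  base <- predict(model, X, type = "response")
  changes <- vapply(seq_len(ncol(X)), function(j) {
    Xr <- X
    Xr[, j] <- means[j]
    mean(abs(predict(model, Xr, type = "response") - base))
  }, numeric(1))
  names(changes) <- names(means) %||% colnames(X)
  changes
}

#' Aggregate replicate sensitivity analyses and rank features
#'
#' Feature-wise mean over replicates, descending rank (ties broken by
#' feature name order), and a top-`k` flag.
#'
#' @param per_replicate list of named change vectors from
#'   [mean_replacement_sensitivity()] sharing one feature schema.
#' @param top_k how many leading features to flag, default 20.
#' @return an object of class `sensitivity_report`: a data.frame with
#'   columns `feature`, `mean_change`, `rank`, `top`, plus the per-replicate
#'   matrix as an attribute.
#' @export
aggregate_and_rank <- function(per_replicate, top_k = 20) {
  if (length(per_replicate) < 1) stop("at least one replicate required")
  nms <- names(per_replicate[[1]])
  for (r in per_replicate)
    if (!identical(names(r), nms)) stop("replicate feature schemas differ")
  M <- do.call(rbind, per_replicate)
  mean_change <- colMeans(M)
  ord <- order(-mean_change, nms)
  rank <- integer(length(nms))
  rank[ord] <- seq_along(nms)
  rep <- data.frame(feature = nms, mean_change = mean_change,
                    rank = rank, top = rank <= top_k, row.names = NULL)
  rep <- rep[order(rep$rank), ]
  rownames(rep) <- NULL
  structure(rep, class = c("sensitivity_report", "data.frame"),
            per_replicate = M, top_k = top_k)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d features, top %d flagged\n",
              nrow(x), attr(x, "top_k")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
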