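# The GFE loss: binary cross entropy over the combined (observed +
# generated) batch plus a correction term that re-emphasizes the observed
# positive records, weighted by how unreliable the generated data is
# ((1 - Acc(D(P))), the discriminator's miss rate on observed positives)
# and how reliable the discriminator itself is (Acc(D(N)), its accuracy on
# held-out observed negatives it never saw in adversarial training).

# internal: clamped BCE without user-facing messaging
bce_quiet <- function(p, y, clamp = 1e-12) {
  p <- pmin(pmax(p, clamp), 1 - clamp)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Binary cross entropy
#'
#' Mean of \eqn{-[y \log p + (1-y) \log(1-p)]}. Predictions exactly 0 or 1
#' are clamped at `1e-12` from the boundary (reported via a message), so
#' the loss is always finite.
#'
#' @param predictions scores in `(0,1)`.
#' @param labels binary labels.
#' @return scalar loss.
#' @examples
#' bce(0.5, 1)            # log 2
#' bce(c(.9, .8, .2, .6), c(1, 1, 1, 1))
#' @export
bce <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  if (length(predictions) == 0) stop("empty prediction vector")
  if (any(predictions <= 0 | predictions >= 1))
    message("bce: predictions at the boundary clamped at 1e-12")
  bce_quiet(predictions, labels)
}

#' Discriminator-derived context for the GFE loss
#'
#' @param accP discriminator accuracy on observed positive references.
#' @param accN discriminator accuracy on observed negative references.
#' @param W weight of the observed portion (observed records in the batch
#'   divided by the total training-set size).
#' @return a `gfe_context` list.
#' @export
gfe_context <- function(accP, accN, W) {
  stopifnot(accP >= 0, accP <= 1, accN >= 0, accN <= 1, W >= 0, W <= 1)
  structure(list(accP = accP, accN = accN, W = W), class = "gfe_context")
}

#' GFE loss
#'
#' `BCE(X) + W * (1 - accP) * accN * BCE(X')` where `X` is the whole batch
#' and `X'` the observed positive records within it (`observed_mask == 1`
#' and `label == 1`). When the batch has no observed positives the
#' correction term is 0, and the loss reduces exactly to `BCE(X)` whenever
#' `accP = 1`, `accN = 0`, or `W = 0`. Since every factor of the correction
#' term is nonnegative, `gfe >= bce` always holds.
#'
#' @param predictions scores in `(0,1)`.
#' @param labels binary labels.
#' @param observed_mask 1 for observational records, 0 for generated ones.
#' @param ctx a [gfe_context()].
#' @return scalar loss.
#' @examples
#' gfe(c(.9, .8, .2, .6), c(1, 1, 1, 1), c(1, 1, 0, 0),
#'     gfe_context(accP = 0.8, accN = 0.9, W = 0.5))
#' @export
gfe <- function(predictions, labels, observed_mask, ctx) {
  stopifnot(inherits(ctx, "gfe_context"),
            length(observed_mask) == length(predictions))
  base <- bce_quiet(predictions, labels)
  obs_pos <- observed_mask == 1 & labels == 1
  if (!any(obs_pos)) return(base)
  corr <- ctx$W * (1 - ctx$accP) * ctx$accN *
    bce_quiet(predictions[obs_pos], labels[obs_pos])
  base + corr
}
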