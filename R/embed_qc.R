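# Generative quality control: a deep autoencoder compresses observed and
# generated records to a 3-coordinate embedding (LeakyReLU layers,
# mean-squared reconstruction objective); the energy distance between the
# two embedded clouds quantifies how closely the generated distribution
# tracks the observed one, and per-feature moment concordance plus a
# two-component PCA projection give feature-space diagnostics.

#' Train the QC autoencoder
#'
#' Full-batch Adam training of an autoencoder whose encoder compresses
#' through widths 400, 300, 200, 100 down to a 3-unit bottleneck (at the
#' study's 382-feature width), each layer LeakyReLU-activated, with a
#' mirrored decoder. Trained on the combined observed + generated records
#' (min-max scaled). Errors if fewer than 10 records are supplied or the
#' final-epoch loss does not improve on the first epoch.
#'
#' @param data matrix of records (observed positives plus generated).
#' @param epochs training epochs, default 2000.
#' @param lr Adam learning rate, default 1e-4.
#' @param encoder_widths encoder widths ending at the embedding width 3.
#' @param decoder_widths decoder hidden widths (output restores the input
#'   width).
#' @param leaky_slope LeakyReLU negative slope.
#' @param seed RNG seed; identical seeds give identical loss curves.
#' @return an object of class `qc_autoencoder` with encoder, decoder and
#'   the per-epoch loss curve.
#' @export
qc_autoencoder_fit <- function(data, epochs = 2000, lr = 1e-4,
                               encoder_widths = c(400, 300, 200, 100, 3),
                               decoder_widths = c(100, 200, 300, 400),
                               leaky_slope = 0.01, seed = 1L) {
  X <- as.matrix(data)
  if (nrow(X) < 10) stop("QC autoencoder needs at least 10 records")
  p <- ncol(X)
  k <- encoder_widths[length(encoder_widths)]
  with_seed(seed, {
    enc <- nn_new(c(p, encoder_widths), "lrelu", out_layer = FALSE,
                  leaky_slope = leaky_slope)
    dec <- nn_new(c(k, decoder_widths, p), "lrelu", "linear",
                  leaky_slope = leaky_slope)
    opt_e <- nn_adam_init(enc)
    opt_d <- nn_adam_init(dec)
    losses <- numeric(epochs)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      fe <- nn_forward(enc, X, train = TRUE)
      fd <- nn_forward(dec, fe$output, train = TRUE)
      R <- fd$output
      losses[ep] <- mean((R - X)^2)
      dZ <- 2 * (R - X) / length(X)
      bwd <- nn_backward(dec, fd$cache, dZ, wrt = "preact")
      bwe <- nn_backward(enc, fe$cache, bwd$d_input, wrt = "output")
      st <- nn_adam_step(dec, opt_d, bwd$grads, lr)
      dec <- st$net; opt_d <- st$opt
      st <- nn_adam_step(enc, opt_e, bwe$grads, lr)
      enc <- st$net; opt_e <- st$opt
    }
    if (losses[epochs] >= losses[1])
      stop("QC autoencoder failed to reduce reconstruction loss over training")
    structure(list(enc = enc, dec = dec, p = p, embedding_dim = k,
                   loss_curve = losses, seed = seed),
              class = "qc_autoencoder")
  })
}

#' @export
print.qc_autoencoder <- function(x, ...) {
  cat(sprintf("<qc_autoencoder> %d features -> %d-coordinate embedding, %d epochs\n",
              x$p, x$embedding_dim, length(x$loss_curve)))
  cat(sprintf("  reconstruction loss: %.5f (first) -> %.5f (final)\n",
              x$loss_curve[1], utils::tail(x$loss_curve, 1)))
  invisible(x)
}

#' Embed or reconstruct records with a trained QC autoencoder
#'
#' @param object a `qc_autoencoder`.
#' @param newdata feature matrix.
#' @param type `"embedding"` (n x 3 coordinates) or `"reconstruction"`.
#' @param ... unused.
#' @export
predict.qc_autoencoder <- function(object, newdata,
                                   type = c("embedding", "reconstruction"), ...) {
  type <- match.arg(type)
  Z <- nn_forward(object$enc, as.matrix(newdata), train = FALSE)$output
  if (type == "embedding") Z
  else nn_forward(object$dec, Z, train = FALSE)$output
}

#' Energy distance between embedded observed and generated clouds
#'
#' @param encoder a trained `qc_autoencoder`.
#' @param observed,generated nonempty record matrices.
#' @return nonnegative energy distance in the embedding space.
#' @export
embedding_distance <- function(encoder, observed, generated) {
  energy_distance(predict(encoder, observed),
                  predict(encoder, generated))
}

#' Per-feature moment comparison of observed vs generated records
#'
#' Computes per-feature mean and standard deviation for both sets, their
#' concordance (correlation of the paired values and mean absolute
#' deviation from the line y = x), and the projection of both sets onto
#' the first two principal components of the pooled data.
#'
#' @param observed,generated matrices on the same feature schema.
#' @return an object of class `moment_report` with `moments` (data.frame),
#'   `concordance`, `mad`, and `pca` (scores plus source tags).
#' @export
moment_comparison <- function(observed, generated) {
  O <- as.matrix(observed); G <- as.matrix(generated)
  if (ncol(O) != ncol(G)) stop("observed and generated feature schemas differ")
  moments <- data.frame(
    feature = colnames(O) %||% sprintf("f%d", seq_len(ncol(O))),
    mean_observed = colMeans(O), mean_generated = colMeans(G),
    sd_observed = apply(O, 2, stats::sd), sd_generated = apply(G, 2, stats::sd),
    row.names = NULL)
  xo <- c(moments$mean_observed, moments$sd_observed)
  xg <- c(moments$mean_generated, moments$sd_generated)
  conc <- if (stats::sd(xo) > 0 && stats::sd(xg) > 0) stats::cor(xo, xg) else NA_real_
  pooled <- rbind(O, G)
  keep <- apply(pooled, 2, stats::sd) > 0
  pc <- stats::prcomp(pooled[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  structure(list(moments = moments, concordance = conc,
                 mad = mean(abs(xo - xg)),
                 pca = data.frame(source = rep(c("observed", "generated"),
                                               c(nrow(O), nrow(G))),
                                  PC1 = pc$x[, 1],
                                  PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)),
            class = "moment_report")
}

#' @export
print.moment_report <- function(x, ...) {
  cat(sprintf("<moment_report> %d features; moment concordance %.3f, |y - x| %.4f\n",
              nrow(x$moments), x$concordance, x$mad))
  invisible(x)
}

#' Full embedding QC report
#'
#' Bundles the 3-coordinate embedding with source tags, the autoencoder
#' loss curve, the observed-vs-generated energy distance, and the
#' [moment_comparison()] diagnostics.
#'
#' @param encoder a trained `qc_autoencoder`.
#' @param observed,generated record matrices.
#' @return an object of class `embedding_report`.
#' @export
embedding_report <- function(encoder, observed, generated) {
  EO <- predict(encoder, observed)
  EG <- predict(encoder, generated)
  emb <- data.frame(source = rep(c("observed", "generated"),
                                 c(nrow(EO), nrow(EG))),
                    e1 = c(EO[, 1], EG[, 1]), e2 = c(EO[, 2], EG[, 2]),
                    e3 = c(EO[, 3], EG[, 3]))
  structure(list(embedding = emb, loss_curve = encoder$loss_curve,
                 energy_distance = energy_distance(EO, EG),
                 moments = moment_comparison(observed, generated)),
            class = "embedding_report")
}

#' @export
print.embedding_report <- function(x, ...) {
  cat(sprintf("<embedding_report> %d embedded records; energy distance %.4f\n",
              nrow(x$embedding), x$energy_distance))
  invisible(x)
}
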