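# Adversarial feature-enhancement: a discriminator (dense net with batch
# normalization and a sigmoid score) is trained to label observed positive
# records as real and generator outputs as fake, while the generator -- an
# autoencoder fed real positive records, with Gaussian noise injected at
# its bottleneck -- is trained to make the discriminator score its outputs
# as real (non-saturating objective). Observed negatives are never used at
# any stage of adversarial training; they serve only as a held-out
# reliability check of the trained discriminator.

#' Observational reference sets for discriminator evaluation
#'
#' @param P observed positive records (rows), min-max scaled.
#' @param N observed negative records; never used in adversarial training,
#'   required nonempty before any GFE evaluation.
#' @return a `reference_sets` list.
#' @export
reference_sets <- function(P, N) {
  P <- as.matrix(P); N <- as.matrix(N)
  if (nrow(N) == 0) stop("negative reference set must be nonempty")
  if (ncol(P) != ncol(N)) stop("P and N must share the feature schema")
  structure(list(P = P, N = N), class = "reference_sets")
}

#' Train the adversarial pair on observed positive records
#'
#' Alternating 1:1 full-batch updates for `steps` steps: the discriminator
#' minimizes binary cross entropy labelling observed positives 1 and
#' generator outputs 0; the generator minimizes the binary cross entropy of
#' the discriminator scoring its outputs as 1. Both use Adam. After
#' training the discriminator is frozen: evaluation never mutates weights
#' or normalization statistics.
#'
#' @param positives matrix of observed positive records (min-max scaled,
#'   train + test partitions only). At least 2 rows.
#' @param steps training steps, default 3000.
#' @param lr Adam learning rate, default 0.005.
#' @param weight_decay L2 weight decay, default 1e-4.
#' @param sigma_z standard deviation of the Gaussian noise added at the
#'   generator bottleneck, default 0.1.
#' @param disc_widths discriminator hidden widths, default
#'   `c(200, 200, 200, 100)` (input 382 -> 200 -> 200 -> 200 -> 100 -> 1 at
#'   the study's feature width).
#' @param gen_encoder_widths,gen_decoder_widths generator encoder/decoder
#'   hidden widths, defaults `c(300, 75)` and `c(150)` (bottleneck 75,
#'   output restored to the input width and clipped to `[0,1]`).
#' @param seed RNG seed; identical seeds give identical loss histories.
#' @return an object of class `gan_fit` with the trained pair and per-step
#'   loss history.
#' @export
gan_fit <- function(positives, steps = 3000, lr = 0.005, weight_decay = 1e-4,
                    sigma_z = 0.1, disc_widths = c(200, 200, 200, 100),
                    gen_encoder_widths = c(300, 75),
                    gen_decoder_widths = c(150), seed = 1L) {
  X <- as.matrix(positives)
  if (nrow(X) < 2) stop("adversarial training needs at least 2 positive records")
  p <- ncol(X)
  bottleneck <- gen_encoder_widths[length(gen_encoder_widths)]
  with_seed(seed, {
    disc <- nn_new(c(p, disc_widths, 1), "relu", "sigmoid", batchnorm = TRUE)
    enc <- nn_new(c(p, gen_encoder_widths), "relu", batchnorm = TRUE,
                  out_layer = FALSE)
    dec <- nn_new(c(bottleneck, gen_decoder_widths, p), "relu", "clip01",
                  batchnorm = TRUE)
    opt_d <- nn_adam_init(disc)
    opt_e <- nn_adam_init(enc)
    opt_g <- nn_adam_init(dec)
    n <- nrow(X)
    hist_d <- hist_g <- numeric(steps)
    for (s in seq_len(steps)) {
      # generator forward (train mode, fresh bottleneck noise)
      fe <- nn_forward(enc, X, train = TRUE); enc <- fe$net
      z <- fe$output + sigma_z * matrix(stats::rnorm(n * bottleneck), n, bottleneck)
      fd <- nn_forward(dec, z, train = TRUE); dec <- fd$net
      fake <- fd$output

      # discriminator update on real (label 1) + fake (label 0)
      Xi <- rbind(X, fake)
      yi <- c(rep(1, n), rep(0, n))
      fw <- nn_forward(disc, Xi, train = TRUE); disc <- fw$net
      pr <- as.vector(fw$output)
      hist_d[s] <- bce_quiet(pr, yi)
      dZ <- matrix((pr - yi) / length(yi), ncol = 1)
      bw <- nn_backward(disc, fw$cache, dZ, wrt = "preact")
      st <- nn_adam_step(disc, opt_d, bw$grads, lr, weight_decay)
      disc <- st$net; opt_d <- st$opt

      # generator update: push D(fake) toward 1 through the frozen-for-this-
      # step discriminator (weights not updated; running normalization
      # statistics are used so batch-wide shifts of the fakes stay visible
      # to the generator's gradient)
      fw2 <- nn_forward(disc, fake, train = FALSE)
      pg <- as.vector(fw2$output)
      hist_g[s] <- bce_quiet(pg, rep(1, n))
      dZ2 <- matrix((pg - 1) / n, ncol = 1)
      bw2 <- nn_backward(disc, fw2$cache, dZ2, wrt = "preact")
      bwd <- nn_backward(dec, fd$cache, bw2$d_input, wrt = "output")
      bwe <- nn_backward(enc, fe$cache, bwd$d_input, wrt = "output")
      st <- nn_adam_step(dec, opt_g, bwd$grads, lr, weight_decay)
      dec <- st$net; opt_g <- st$opt
      st <- nn_adam_step(enc, opt_e, bwe$grads, lr, weight_decay)
      enc <- st$net; opt_e <- st$opt
    }
    structure(list(disc = disc, enc = enc, dec = dec, sigma_z = sigma_z,
                   p = p, steps = steps, seed = seed,
                   history = data.frame(step = seq_len(steps),
                                        d_loss = hist_d, g_loss = hist_g)),
              class = "gan_fit")
  })
}

#' @export
print.gan_fit <- function(x, ...) {
  cat(sprintf("<gan_fit> %d-feature adversarial pair, %d steps, sigma_z = %g\n",
              x$p, x$steps, x$sigma_z))
  cat(sprintf("  final losses: discriminator %.4f, generator %.4f\n",
              utils::tail(x$history$d_loss, 1), utils::tail(x$history$g_loss, 1)))
  invisible(x)
}

#' @export
plot.gan_fit <- function(x, ...) {
  plot(x$history$step, x$history$d_loss, type = "l", col = "steelblue",
       xlab = "step", ylab = "loss",
       ylim = range(c(x$history$d_loss, x$history$g_loss)), ...)
  graphics::lines(x$history$step, x$history$g_loss, col = "firebrick")
  graphics::legend("topright", c("discriminator", "generator"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Generate feature-enhanced records
#'
#' Passes resampled observed positives through the trained generator
#' (encoder, bottleneck noise of scale `sigma_z`, decoder) using frozen
#' normalization statistics. Outputs lie in `[0, 1]`.
#'
#' @param bundle a trained `gan_fit`.
#' @param positives matrix of observed positive records to resample from.
#' @param n number of records to generate, default 2600.
#' @param seed RNG seed.
#' @return an `n x p` matrix of generated records.
#' @export
generate_records <- function(bundle, positives, n = 2600, seed = 1L) {
  stopifnot(inherits(bundle, "gan_fit"))
  if (n <= 0) stop("n must be positive")
  X <- as.matrix(positives)
  if (ncol(X) != bundle$p) stop("feature width does not match the trained pair")
  with_seed(seed, {
    idx <- sample.int(nrow(X), n, replace = TRUE)
    z <- nn_forward(bundle$enc, X[idx, , drop = FALSE], train = FALSE)$output
    if (bundle$sigma_z > 0)
      z <- z + bundle$sigma_z * matrix(stats::rnorm(length(z)), nrow(z), ncol(z))
    out <- nn_forward(bundle$dec, z, train = FALSE)$output
    rownames(out) <- sprintf("G%05d", seq_len(n))
    out
  })
}

#' Frozen-discriminator scores
#'
#' @param bundle a trained `gan_fit`.
#' @param records matrix of records.
#' @return vector of scores in `(0, 1)`; repeated calls on the same records
#'   are identical (evaluation never mutates the discriminator).
#' @export
discriminator_scores <- function(bundle, records) {
  stopifnot(inherits(bundle, "gan_fit"))
  as.vector(nn_forward(bundle$disc, as.matrix(records), train = FALSE)$output)
}

#' Discriminator accuracy on a reference set
#'
#' Fraction of records scored on the expected side of 0.5: a record counts
#' as correct when its score is `>= 0.5` (`expected = "real"`) or `< 0.5`
#' (`expected = "fake"`). `Acc(D(P))` is the accuracy on observed positive
#' references with `expected = "real"`; `Acc(D(N))` the accuracy on observed
#' negative references with `expected = "fake"`.
#'
#' @param bundle a trained `gan_fit`.
#' @param records nonempty matrix of records.
#' @param expected `"real"` or `"fake"`.
#' @return fraction in `[0, 1]`.
#' @export
discriminator_accuracy <- function(bundle, records, expected = c("real", "fake")) {
  expected <- match.arg(expected)
  records <- as.matrix(records)
  if (nrow(records) == 0) stop("empty record set")
  sc <- discriminator_scores(bundle, records)
  if (expected == "real") mean(sc >= 0.5) else mean(sc < 0.5)
}
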