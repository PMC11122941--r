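# Minimal feed-forward network engine: dense layers, optional batch
# normalization placed after the activation, ReLU / LeakyReLU / sigmoid /
# linear / clipped-linear activations, and Adam with L2 weight decay.
# All models in the package (discriminator, autoencoder generator, QC
# autoencoder, MLP predictor) are built from these pieces; the backward
# pass is verified against finite differences in the test suite.

nn_act <- function(z, type, slope = 0.01) {
  switch(type,
    relu    = pmax(z, 0),
    lrelu   = ifelse(z > 0, z, slope * z),
    sigmoid = 1 / (1 + exp(-z)),
    linear  = z,
    clip01  = pmin(pmax(z, 0), 1),
    stop("unknown activation: ", type)
  )
}

# derivative of the activation w.r.t. its pre-activation input
nn_act_grad <- function(z, a, type, slope = 0.01) {
  switch(type,
    relu    = (z > 0) * 1,
    lrelu   = ifelse(z > 0, 1, slope),
    sigmoid = a * (1 - a),
    linear  = matrix(1, nrow(z), ncol(z)),
    clip01  = (z > 0 & z < 1) * 1,
    stop("unknown activation: ", type)
  )
}

#' Construct an untrained feed-forward network
#'
#' @param sizes integer vector of layer widths, input first.
#' @param hidden_activation activation for hidden-style layers.
#' @param output_activation activation for the final layer when
#'   `out_layer = TRUE`.
#' @param batchnorm apply batch normalization after the activation of every
#'   hidden-style layer.
#' @param out_layer if `FALSE` every layer (including the last) is
#'   hidden-style (activation + optional batch norm), as in an encoder
#'   whose bottleneck is itself activated.
#' @param leaky_slope negative-side slope for `lrelu`.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `ff_net`.
#' @keywords internal
nn_new <- function(sizes, hidden_activation = "relu", output_activation = "sigmoid",
                   batchnorm = FALSE, out_layer = TRUE, leaky_slope = 0.01,
                   seed = NULL) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  L <- length(sizes) - 1L
  layers <- with_seed(seed, lapply(seq_len(L), function(l) {
    fan_in <- sizes[l]
    hidden_style <- l < L || !out_layer
    act <- if (hidden_style) hidden_activation else output_activation
    sd0 <- sqrt(2 / fan_in)  # He initialization, suited to ReLU family
    layer <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sd0), fan_in, sizes[l + 1]),
      b = numeric(sizes[l + 1]),
      act = act,
      bn = NULL
    )
    if (batchnorm && hidden_style) {
      layer$bn <- list(gamma = rep(1, sizes[l + 1]), beta = numeric(sizes[l + 1]),
                       rmean = numeric(sizes[l + 1]), rvar = rep(1, sizes[l + 1]))
    }
    layer
  }))
  structure(list(layers = layers, sizes = sizes, leaky_slope = leaky_slope),
            class = "ff_net")
}

#' Forward pass
#'
#' @param net an `ff_net`.
#' @param X n x p input matrix.
#' @param train use batch statistics (and update running statistics) in
#'   batch-norm layers; `FALSE` uses frozen running statistics, so repeated
#'   evaluation of a trained network is deterministic.
#' @param momentum running-statistics update rate.
#' @return list with `output`, `cache` (for backward), and the possibly
#'   updated `net`.
#' @keywords internal
nn_forward <- function(net, X, train = FALSE, momentum = 0.1) {
  eps <- 1e-5
  H <- as.matrix(X)
  cache <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- add_row(H %*% ly$W, ly$b)
    A <- nn_act(Z, ly$act, net$leaky_slope)
    bnc <- NULL
    if (!is.null(ly$bn)) {
      if (train) {
        n <- nrow(A)
        mu <- colMeans(A)
        va <- colMeans(add_row(A, -mu)^2)
        net$layers[[l]]$bn$rmean <- (1 - momentum) * ly$bn$rmean + momentum * mu
        net$layers[[l]]$bn$rvar  <- (1 - momentum) * ly$bn$rvar + momentum * va
      } else {
        mu <- ly$bn$rmean
        va <- ly$bn$rvar
      }
      xhat <- add_row(A, -mu) / matrix(sqrt(va + eps), nrow(A), ncol(A), byrow = TRUE)
      Hout <- add_row(xhat * matrix(ly$bn$gamma, nrow(A), ncol(A), byrow = TRUE), ly$bn$beta)
      bnc <- list(xhat = xhat, var = va, eps = eps, train = train)
    } else {
      Hout <- A
    }
    cache[[l]] <- list(X = H, Z = Z, A = A, bn = bnc)
    H <- Hout
  }
  list(output = H, cache = cache, net = net)
}

#' Backward pass
#'
#' @param net,cache network and forward cache (train-mode cache for
#'   batch-norm layers).
#' @param d_out gradient of the loss; `wrt = "preact"` means w.r.t. the
#'   final layer's pre-activation (the usual shortcut for sigmoid + BCE or
#'   linear + MSE heads), `wrt = "output"` means w.r.t. the final layer's
#'   output.
#' @return list with per-layer `grads` (dW, db, dgamma, dbeta) and `d_input`,
#'   the gradient w.r.t. the network input (used to chain the generator
#'   through the discriminator).
#' @keywords internal
nn_backward <- function(net, cache, d_out, wrt = c("preact", "output")) {
  wrt <- match.arg(wrt)
  L <- length(net$layers)
  grads <- vector("list", L)
  dH <- d_out
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    if (l == L && wrt == "preact") {
      if (!is.null(ly$bn)) stop("preact shortcut not valid for a batch-normalized top layer")
      dZ <- dH
      dgamma <- dbeta <- NULL
    } else {
      if (!is.null(ly$bn)) {
        bnc <- cc$bn
        dgamma <- colSums(dH * bnc$xhat)
        dbeta <- colSums(dH)
        gmat <- matrix(ly$bn$gamma, nrow(dH), ncol(dH), byrow = TRUE)
        dxhat <- dH * gmat
        inv_sd <- matrix(1 / sqrt(bnc$var + bnc$eps), nrow(dH), ncol(dH), byrow = TRUE)
        if (isTRUE(bnc$train)) {
          n <- nrow(dH)
          dA <- inv_sd / n *
            (n * dxhat -
               matrix(colSums(dxhat), n, ncol(dH), byrow = TRUE) -
               bnc$xhat * matrix(colSums(dxhat * bnc$xhat), n, ncol(dH), byrow = TRUE))
        } else {
          dA <- dxhat * inv_sd  # frozen statistics: plain affine map
        }
      } else {
        dgamma <- dbeta <- NULL
        dA <- dH
      }
      dZ <- dA * nn_act_grad(cc$Z, cc$A, ly$act, net$leaky_slope)
    }
    grads[[l]] <- list(dW = crossprod(cc$X, dZ), db = colSums(dZ),
                       dgamma = dgamma, dbeta = dbeta)
    dH <- dZ %*% t(ly$W)
  }
  list(grads = grads, d_input = dH)
}

nn_adam_init <- function(net) {
  st <- lapply(net$layers, function(ly) {
    s <- list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    if (!is.null(ly$bn)) {
      s$mg <- ly$bn$gamma * 0; s$vg <- ly$bn$gamma * 0
      s$mB <- ly$bn$beta * 0; s$vB <- ly$bn$beta * 0
    }
    s
  })
  list(t = 0L, layers = st)
}

# One Adam step; weight decay is applied as an L2 gradient term on the
# dense weights only.
nn_adam_step <- function(net, opt, grads, lr, weight_decay = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(param, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    param <- param - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(param = param, m = m, v = v)
  }
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    st <- opt$layers[[l]]
    u <- upd(net$layers[[l]]$W, g$dW + weight_decay * net$layers[[l]]$W, st$mW, st$vW)
    net$layers[[l]]$W <- u$param; st$mW <- u$m; st$vW <- u$v
    u <- upd(net$layers[[l]]$b, g$db, st$mb, st$vb)
    net$layers[[l]]$b <- u$param; st$mb <- u$m; st$vb <- u$v
    if (!is.null(net$layers[[l]]$bn)) {
      u <- upd(net$layers[[l]]$bn$gamma, g$dgamma, st$mg, st$vg)
      net$layers[[l]]$bn$gamma <- u$param; st$mg <- u$m; st$vg <- u$v
      u <- upd(net$layers[[l]]$bn$beta, g$dbeta, st$mB, st$vB)
      net$layers[[l]]$bn$beta <- u$param; st$mB <- u$m; st$vB <- u$v
    }
    opt$layers[[l]] <- st
  }
  list(net = net, opt = opt)
}
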