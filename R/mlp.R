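# MLP predictor trained on the combined observed + generated data with
# either plain binary cross entropy or the GFE loss. The discriminator
# reliability factors Acc(D(P)) and Acc(D(N)) are refreshed once per epoch
# from the frozen discriminator; the observed-portion weight W is
# recomputed per batch as (observed records in batch) / (total training
# records).

#' Train the prediction MLP
#'
#' Mini-batch Adam training of a dense network whose hidden widths default
#' to the input width halved, quartered, and eighthed (382 -> 191 -> 95 ->
#' 47 -> 1 at the study's feature width), sigmoid output. With
#' `loss = "gfe"` each batch's loss is
#' `BCE(X) + W (1 - accP) accN BCE(X')`, with `X'` the observed positives
#' in the batch; gradients weight those records accordingly.
#'
#' @param X training feature matrix (min-max scaled).
#' @param y binary labels (generated records enter labelled 1).
#' @param observed_mask 1 for observational records, 0 for generated /
#'   synthetic ones. Default all observed.
#' @param loss `"bce"` or `"gfe"`.
#' @param gan a trained [gan_fit()] (required for `loss = "gfe"` unless
#'   `ctx` is supplied).
#' @param refs a [reference_sets()] with observed positives `P` and
#'   negatives `N` for the per-epoch accuracy refresh.
#' @param ctx optional fixed `list(accP =, accN =)` overriding the
#'   discriminator refresh (pinning `accP = 1` reproduces the BCE
#'   trajectory exactly).
#' @param hidden hidden widths; default `floor(p / c(2, 4, 8))`.
#' @param lr,weight_decay,epochs,batch_size Adam hyperparameters; defaults
#'   5e-5, 1e-4, 200 epochs, batch 64.
#' @param eval_sets optional named list of `list(X =, y =)` evaluation sets
#'   whose accuracy is recorded per epoch (e.g. test, validation).
#' @param seed RNG seed; identical seeds give identical curves.
#' @return an object of class `mlp_fit` with the trained network, per-epoch
#'   `curves` (loss, accuracies, accP/accN/W diagnostics), and metadata.
#' @export
mlp_fit <- function(X, y, observed_mask = NULL, loss = c("bce", "gfe"),
                    gan = NULL, refs = NULL, ctx = NULL, hidden = NULL,
                    lr = 5e-5, weight_decay = 1e-4, epochs = 200,
                    batch_size = 64, eval_sets = NULL, seed = 1L) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(observed_mask)) observed_mask <- rep(1L, n)
  stopifnot(length(y) == n, length(observed_mask) == n)
  if (loss == "gfe" && is.null(ctx) && (is.null(gan) || is.null(refs)))
    stop("loss = 'gfe' requires a trained gan and reference sets (or a fixed ctx)")
  p <- ncol(X)
  if (is.null(hidden)) hidden <- pmax(floor(p / c(2, 4, 8)), 1)
  acc_of <- function(net, M, lab) {
    pr <- as.vector(nn_forward(net, M, train = FALSE)$output)
    mean((pr >= 0.5) == (lab == 1))
  }
  with_seed(seed, {
    net <- nn_new(c(p, hidden, 1), "relu", "sigmoid", batchnorm = FALSE)
    opt <- nn_adam_init(net)
    curves <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      if (loss == "gfe") {
        accP <- if (!is.null(ctx)) ctx$accP else
          discriminator_accuracy(gan, refs$P, "real")
        accN <- if (!is.null(ctx)) ctx$accN else
          discriminator_accuracy(gan, refs$N, "fake")
      } else accP <- accN <- NA_real_
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      ep_loss <- 0; ep_W <- NA_real_
      for (b in starts) {
        idx <- ord[b:min(b + batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- nn_forward(net, Xb, train = TRUE)
        pr <- as.vector(fw$output)
        w <- rep(1 / length(idx), length(idx))
        if (loss == "gfe") {
          Wb <- sum(observed_mask[idx] == 1) / n
          ep_W <- Wb
          obs_pos <- observed_mask[idx] == 1 & yb == 1
          lv <- bce_quiet(pr, yb)
          if (any(obs_pos)) {
            cfac <- Wb * (1 - accP) * accN
            w[obs_pos] <- w[obs_pos] + cfac / sum(obs_pos)
            lv <- lv + cfac * bce_quiet(pr[obs_pos], yb[obs_pos])
          }
        } else lv <- bce_quiet(pr, yb)
        ep_loss <- ep_loss + lv * length(idx)
        dZ <- matrix((pr - yb) * w, ncol = 1)
        bw <- nn_backward(net, fw$cache, dZ, wrt = "preact")
        st <- nn_adam_step(net, opt, bw$grads, lr, weight_decay)
        net <- st$net; opt <- st$opt
      }
      row <- list(epoch = ep, loss = ep_loss / n,
                  acc_train = acc_of(net, X, y),
                  accP = accP, accN = accN, W = ep_W)
      if (!is.null(eval_sets)) for (nm in names(eval_sets))
        row[[paste0("acc_", nm)]] <- acc_of(net, eval_sets[[nm]]$X, eval_sets[[nm]]$y)
      curves[[ep]] <- as.data.frame(row)
    }
    structure(list(net = net, hidden = hidden, loss = loss, p = p,
                   features = colnames(X),
                   curves = do.call(rbind, curves), seed = seed),
              class = "mlp_fit")
  })
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("<mlp_fit> %d -> %s -> 1, loss = %s, %d epochs\n",
              x$p, paste(x$hidden, collapse = " -> "), x$loss, nrow(x$curves)))
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              utils::tail(x$curves$loss, 1), utils::tail(x$curves$acc_train, 1)))
  invisible(x)
}

#' @export
summary.mlp_fit <- function(object, ...) {
  print(object)
  acc_cols <- grep("^acc_", names(object$curves), value = TRUE)
  cat("  final accuracies:\n")
  for (a in acc_cols)
    cat(sprintf("    %s: %.3f\n", sub("acc_", "", a),
                utils::tail(object$curves[[a]], 1)))
  invisible(object)
}

#' @export
plot.mlp_fit <- function(x, ...) {
  acc_cols <- grep("^acc_", names(x$curves), value = TRUE)
  cols <- seq_along(acc_cols) + 1
  plot(x$curves$epoch, x$curves[[acc_cols[1]]], type = "l", col = cols[1],
       ylim = c(0, 1), xlab = "epoch", ylab = "accuracy", ...)
  for (i in seq_along(acc_cols)[-1])
    graphics::lines(x$curves$epoch, x$curves[[acc_cols[i]]], col = cols[i])
  graphics::legend("bottomright", sub("acc_", "", acc_cols), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Predict from a trained MLP
#'
#' @param object an `mlp_fit`.
#' @param newdata feature matrix on the training scale.
#' @param type `"response"` (sigmoid score) or `"class"` (0/1 at 0.5).
#' @param ... unused.
#' @return numeric scores or integer classes.
#' @export
predict.mlp_fit <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  sc <- as.vector(nn_forward(object$net, as.matrix(newdata), train = FALSE)$output)
  if (type == "response") sc else as.integer(sc >= 0.5)
}

#' Evaluate a classifier on a labelled set
#'
#' Thresholds scores at 0.5 and reports the confusion matrix, per-class
#' accuracies, balanced accuracy (their mean), and sensitivity. When a
#' class is absent from the evaluation set its per-class accuracy -- and
#' hence the balanced accuracy -- is reported as `NA`.
#'
#' @param model anything with a `predict(model, X, type = "response")`
#'   method returning positive-class scores.
#' @param X feature matrix.
#' @param y binary labels (nonempty).
#' @return an object of class `eval_report`.
#' @export
evaluate <- function(model, X, y) {
  if (length(y) == 0) stop("empty evaluation set")
  sc <- predict(model, X, type = "response")
  pred <- as.integer(sc >= 0.5)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  acc_pos <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  acc_neg <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 per_class = c(positive = acc_pos, negative = acc_neg),
                 balanced_accuracy = mean(c(acc_pos, acc_neg)),
                 sensitivity = acc_pos,
                 accuracy = (tp + tn) / length(y), n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d  TP=%d FP=%d TN=%d FN=%d\n", x$n,
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  cat(sprintf("  per-class accuracy: positive %.3f, negative %.3f\n",
              x$per_class["positive"], x$per_class["negative"]))
  cat(sprintf("  balanced accuracy %.3f, sensitivity %.3f\n",
              x$balanced_accuracy, x$sensitivity))
  invisible(x)
}

#' Fit a conventional baseline classifier
#'
#' Fits one of the comparison families at default settings on observed data
#' only (no augmentation): decision tree, random forest, support vector
#' machine, or k-nearest neighbours. Under severe class imbalance with no
#' feature signal these collapse to the majority class.
#'
#' @param family one of `"decision-tree"`, `"random-forest"`, `"svm"`,
#'   `"knn"`.
#' @param X feature matrix.
#' @param y binary labels.
#' @param seed RNG seed for the stochastic families.
#' @return an object of class `baseline_fit` with a `predict` method.
#' @export
train_baseline <- function(family = c("decision-tree", "random-forest",
                                      "svm", "knn"),
                           X, y, seed = 1L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty training set")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%04d", seq_len(ncol(X)))
  yf <- factor(y, levels = c(0, 1))
  fit <- with_seed(seed, switch(family,
    "random-forest" = randomForest::randomForest(x = X, y = yf),
    "svm" = e1071::svm(x = X, y = yf, probability = TRUE),
    "decision-tree" = {
      df <- data.frame(.y = yf, X, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    "knn" = list(train = X, cl = yf, k = 5)
  ))
  structure(list(family = family, fit = fit, features = colnames(X)),
            class = "baseline_fit")
}

#' @export
predict.baseline_fit <- function(object, newdata,
                                 type = c("response", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  colnames(newdata) <- object$features
  sc <- switch(object$family,
    "random-forest" = stats::predict(object$fit, newdata, type = "prob")[, "1"],
    "svm" = {
      pr <- stats::predict(object$fit, newdata, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    "decision-tree" = {
      df <- as.data.frame(newdata)
      names(df) <- object$features %||% names(df)
      stats::predict(object$fit, df, type = "prob")[, "1"]
    },
    "knn" = {
      pr <- class::knn(object$fit$train, newdata, object$fit$cl,
                       k = object$fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    })
  if (type == "response") as.numeric(sc) else as.integer(sc >= 0.5)
}
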