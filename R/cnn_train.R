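# Training: Adam on softmax cross-entropy. The optimizer is not specified by
# the architecture itself; Adam with learning rate 1e-3 and batch size 64 is
# the package default and everything is configurable.

mi_cnn_backward <- function(model, cache, shapes, dprob_logits) {
  grads <- list()
  da <- dprob_logits
  for (nm in rev(names(model$layers))) {
    l <- model$layers[[nm]]
    da <- switch(
      l$type,
      softmax = da,                     # combined with cross-entropy below
      dense = {
        cc <- cache[[nm]]
        grads[[nm]] <- list(dW = da %*% t(cc$x), db = rowSums(da))
        crossprod(l$W, da)
      },
      flatten = {
        prev <- shapes[[which(names(shapes) == nm) - 1L]]
        array(da, dim = prev)
      },
      dropout = {
        if (!is.null(cache[[nm]])) apply_channel_mask(da, cache[[nm]]$mask)
        else da
      },
      avgpool = avgpool_backward(da, l$k_h, l$k_w, cache[[nm]]$in_dim),
      activation = elu_backward(cache[[nm]]$y, da),
      batchnorm = bn_backward(cache[[nm]], da),
      conv = {
        bk <- conv_backward(l, cache[[nm]]$x, da)
        grads[[nm]] <- list(dW = bk$dW, db = bk$db)
        bk$dx
      },
      input = da
    )
  }
  grads
}

adam_init <- function(model) {
  st <- list()
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    if (!is.null(l$W))
      st[[nm]] <- list(mW = l$W * 0, vW = l$W * 0,
                       mb = l$b * 0, vb = l$b * 0)
  }
  st
}

adam_step <- function(model, grads, st, lr, beta1, beta2, eps, t) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    s <- st[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    c1 <- 1 - beta1^t
    c2 <- 1 - beta2^t
    model$layers[[nm]]$W <- model$layers[[nm]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    model$layers[[nm]]$b <- model$layers[[nm]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    st[[nm]] <- s
  }
  list(model = model, st = st)
}

#' Train the compact CNN
#'
#' Mini-batch Adam on softmax cross-entropy, deterministic given `seed`
#' (shuffling, dropout and initialization all draw from R's RNG). Batch
#' statistics are used for normalization during training; exponential
#' running statistics are used at evaluation time.
#'
#' @param model an `mi_cnn` from [build_mi_cnn()].
#' @param train an `mi_samples` training set.
#' @param test optional `mi_samples`; per-epoch test accuracy is recorded.
#' @param epochs training epochs.
#' @param batch mini-batch size.
#' @param lr,beta1,beta2,eps Adam hyper-parameters.
#' @param seed RNG seed.
#' @param verbose print one line per epoch.
#' @return The trained `mi_cnn`, with `history` (tibble: `epoch`,
#'   `train_loss`, `test_acc`) attached.
#' @export
train_mi_cnn <- function(model, train, test = NULL, epochs = 30, batch = 64,
                         lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "mi_cnn"), inherits(train, "mi_samples"))
  n <- dim(train$x)[3]
  if (n == 0) stop("empty training set")
  y_idx <- match(train$meta$class, model$classes)
  if (anyNA(y_idx)) stop("unknown class label in training set")
  set.seed(seed)
  st <- adam_init(model)
  hist <- vector("list", epochs)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (s in seq(1L, n, by = batch)) {
      take <- ord[s:min(n, s + batch - 1L)]
      xb <- train$x[, , take, drop = FALSE]
      yb <- y_idx[take]
      fw <- mi_cnn_forward(model, xb, train = TRUE, keep_cache = TRUE)
      loss <- cross_entropy(fw$prob, yb)
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", ep,
             " (learning rate ", lr, ")")
      losses <- c(losses, loss)
      # update batchnorm running statistics
      for (nm in names(model$layers)) {
        l <- model$layers[[nm]]
        if (l$type == "batchnorm") {
          cc <- fw$cache[[nm]]
          model$layers[[nm]]$run_mean <-
            (1 - l$momentum) * l$run_mean + l$momentum * cc$mu
          model$layers[[nm]]$run_var <-
            (1 - l$momentum) * l$run_var + l$momentum * cc$v
        }
      }
      dlogits <- fw$prob
      dlogits[cbind(yb, seq_along(yb))] <-
        dlogits[cbind(yb, seq_along(yb))] - 1
      dlogits <- dlogits / length(yb)
      grads <- mi_cnn_backward(model, fw$cache, fw$shapes, dlogits)
      step <- step + 1L
      upd <- adam_step(model, grads, st, lr, beta1, beta2, eps, step)
      model <- upd$model
      st <- upd$st
    }
    acc <- if (!is.null(test)) evaluate_mi_cnn(model, test) else NA_real_
    hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(losses),
                                 test_acc = acc)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  test acc %s", ep, mean(losses),
                      ifelse(is.na(acc), "-", sprintf("%.3f", acc))))
  }
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Class probabilities / evaluation
#'
#' `predict` returns per-sample class probabilities; `evaluate_mi_cnn`
#' returns the fraction of samples whose argmax prediction matches the
#' label.
#'
#' @param object,model a trained `mi_cnn`.
#' @param samples an `mi_samples`.
#' @param ... unused.
#' @return `predict`: tibble of `sample`, one probability column per class,
#'   `predicted`; `evaluate_mi_cnn`: scalar accuracy in `[0, 1]`.
#' @export
predict.mi_cnn <- function(object, samples, ...) {
  stopifnot(inherits(samples, "mi_samples"))
  n <- dim(samples$x)[3]
  probs <- matrix(0, nrow = length(object$classes), ncol = n)
  for (s in seq(1L, n, by = 256L)) {          # bounded memory
    e <- min(n, s + 255L)
    fw <- mi_cnn_forward(object, samples$x[, , s:e, drop = FALSE],
                         train = FALSE)
    probs[, s:e] <- fw$prob
  }
  out <- tibble::as_tibble(stats::setNames(as.data.frame(t(probs)),
                                           object$classes))
  out$sample <- samples$meta$sample
  out$predicted <- object$classes[apply(probs, 2, which.max)]
  dplyr::relocate(out, "sample")
}

#' @rdname predict.mi_cnn
#' @export
evaluate_mi_cnn <- function(model, samples) {
  pr <- predict(model, samples)
  mean(pr$predicted == samples$meta$class)
}

#' Broom-style accessors for a fitted CNN
#'
#' `tidy()` returns the per-epoch training history (or the layer table for
#' an untrained model); `glance()` a one-row model summary.
#'
#' @param x an `mi_cnn`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mi_cnn <- function(x, ...) {
  if (!is.null(x$history)) x$history
  else model_param_counts(x)
}

#' @rdname tidy.mi_cnn
#' @export
glance.mi_cnn <- function(x, ...) {
  tibble::tibble(
    n_params = sum(model_param_counts(x)$params),
    n_layers = nrow(x$spec),
    trained = !is.null(x$history),
    epochs = if (!is.null(x$history)) nrow(x$history) else 0L,
    final_loss = if (!is.null(x$history))
      x$history$train_loss[nrow(x$history)] else NA_real_,
    best_acc = if (!is.null(x$history) && any(!is.na(x$history$test_acc)))
      max(x$history$test_acc, na.rm = TRUE) else NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
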