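#' Train a GGENet classifier
#'
#' Supervised training of any GGENet variant with cross-entropy loss and the
#' Adam optimizer, following the experimental protocol's settings (defaults:
#' 100 epochs, learning rate 0.001, batch size 16). Per-epoch training and
#' validation loss/accuracy are recorded; the weights with the best
#' validation accuracy are retained alongside the final weights (metrics are
#' reported from the best-validation checkpoint).
#'
#' @param x training inputs: a `(N, 3, H, W)` feature map of preprocessed
#'   images (see [preprocess()]/[load_images()]).
#' @param y integer class labels `1..K` (or a factor).
#' @param spec a [ggenet_spec()]; `spec$n_classes` must match the labels.
#' @param epochs,lr,batch_size optimizer settings.
#' @param val split for model selection: indices into `x` used as validation
#'   set (excluded from training), or `NULL` for none (final weights used).
#' @param seed seed controlling initialization and batch shuffling.
#' @param classes optional character vector of class names.
#' @param verbose print per-epoch progress.
#' @return an object of class `ggenet_fit` with components `network` (best),
#'   `final_network`, `history` (per-epoch data.frame), `config`, `classes`.
#' @seealso [predict.ggenet_fit()], [evaluate()], [ggenet_distill()]
#' @export
ggenet_fit <- function(x, y, spec, epochs = 100, lr = 1e-3, batch_size = 16,
                       val = NULL, seed = 1, classes = NULL, verbose = FALSE) {
  x <- as_feature_map(x)
  if (is.factor(y)) { classes <- classes %||% levels(y); y <- as.integer(y) }
  y <- as.integer(y)
  stopifnot(length(y) == dim(x)[1])
  if (!length(y)) stop("empty training set")
  if (max(y) > spec$n_classes)
    stop("labels exceed spec$n_classes")
  if (!is.null(val)) {
    vx <- x[val, , , , drop = FALSE]; vy <- y[val]
    keep <- setdiff(seq_along(y), val)
    x <- x[keep, , , , drop = FALSE]; y <- y[keep]
  }
  if (!length(y)) stop("empty training set")
  net <- build_ggenet(spec, seed = seed)
  opt <- adam_init_net(net)
  N <- length(y)
  hist_rows <- vector("list", epochs)
  best_acc <- -Inf; best_net <- net
  for (ep in seq_len(epochs)) {
    set.seed(seed * 10000L + ep)
    ord <- sample(N)
    tot_loss <- 0; tot_correct <- 0
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      fw <- net_fwd(net, x[b, , , , drop = FALSE], want_cache = TRUE)
      ce <- cross_entropy(fw$logits, y[b])
      bk <- net_bwd(net, fw$caches, ce$glogits)
      st <- adam_step_net(net, bk$grads, opt, lr = lr)
      net <- st$net; opt <- st$state
      tot_loss <- tot_loss + ce$loss * length(b)
      tot_correct <- tot_correct +
        sum(max.col(fw$logits, ties.method = "first") == y[b])
    }
    row <- data.frame(epoch = ep, train_loss = tot_loss / N,
                      train_acc = tot_correct / N,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      vl <- ggenet_forward(net, vx)
      vce <- cross_entropy(vl, vy)
      row$val_loss <- vce$loss
      row$val_acc <- mean(max.col(vl, ties.method = "first") == vy)
      if (row$val_acc >= best_acc) { best_acc <- row$val_acc; best_net <- net }
    }
    hist_rows[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f%s", ep, row$train_loss,
                      row$train_acc,
                      if (!is.null(val)) sprintf("  val %.4f", row$val_acc) else ""))
  }
  if (is.null(val)) best_net <- net
  structure(list(network = best_net, final_network = net,
                 history = do.call(rbind, hist_rows),
                 config = list(epochs = epochs, lr = lr,
                               batch_size = batch_size, seed = seed,
                               optimizer = "adam", loss = "cross-entropy",
                               normalization = imagenet_stats()),
                 spec = spec,
                 classes = classes %||% as.character(seq_len(spec$n_classes))),
            class = "ggenet_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict method for fitted GGENet models
#'
#' @param object a `ggenet_fit`.
#' @param newdata feature map `(N, 3, H, W)`.
#' @param type `"prob"` (softmax probabilities), `"class"` (factor of
#'   predicted classes), or `"logits"`.
#' @param ... unused.
#' @return matrix of probabilities/logits or a factor of classes.
#' @export
predict.ggenet_fit <- function(object, newdata, type = c("prob", "class", "logits"),
                               ...) {
  type <- match.arg(type)
  logits <- ggenet_forward(object$network, as_feature_map(newdata))
  switch(type,
         logits = logits,
         prob = exp(log_softmax(logits)),
         class = factor(object$classes[max.col(logits, ties.method = "first")],
                        levels = object$classes))
}

#' @export
print.ggenet_fit <- function(x, ...) {
  cat("GGENet classifier\n")
  print(x$spec)
  h <- x$history[nrow(x$history), ]
  cat(sprintf("trained %d epochs; final train acc %.4f%s\n", h$epoch,
              h$train_acc,
              if (!is.na(h$val_acc)) sprintf(", best val acc %.4f",
                                             max(x$history$val_acc, na.rm = TRUE))
              else ""))
  invisible(x)
}

#' @export
summary.ggenet_fit <- function(object, ...) {
  cat("GGENet classifier\n")
  print(object$spec)
  cat(sprintf("parameters: %s\n",
              format(count_parameters(object$network), big.mark = ",")))
  cat(sprintf("config: %d epochs, lr %g, batch %d, seed %d\n",
              object$config$epochs, object$config$lr, object$config$batch_size,
              object$config$seed))
  cat("history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.ggenet_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training history", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
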