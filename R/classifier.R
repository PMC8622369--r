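#' Classifier specification
#'
#' The pipeline treats the classification backbone as a pluggable black
#' box. The bundled `reference_small_cnn` is a compact fully-convolutional
#' network — three 3x3 stride-2 conv blocks (16/32/64 filters, ReLU),
#' global average pooling, and a softmax head — that accepts any input of
#' at least 8x8 pixels, so raw images and `H/4 x W/4` latents train
#' without resizing. Named large backbones (`vgg`, `resnet`, `densenet`,
#' `mobilenet`) are accepted by the interface but require pretrained
#' weights; when those are not installed, [fit_classifier()] raises an
#' explicit capability error rather than silently substituting.
#'
#' @param n_classes number of classes `N >= 2`.
#' @param backbone backbone name; default `"reference_small_cnn"`.
#' @param pretrained load pretrained backbone weights (only meaningful for
#'   the named large backbones).
#' @param learning_rate,batch_size,max_epochs,patience,validation_fraction,seed
#'   training settings, mirroring [cae_train_settings()]: Adam, stratified
#'   10% validation, early stopping on validation loss with best-epoch
#'   restoration.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(n_classes,
                            backbone = c("reference_small_cnn", "vgg",
                                         "resnet", "densenet", "mobilenet"),
                            pretrained = FALSE, learning_rate = 1e-3,
                            batch_size = 32L, max_epochs = 30L,
                            patience = 10L, validation_fraction = 0.1,
                            seed = 1L) {
  backbone <- match.arg(backbone)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("`n_classes` must be >= 2", call. = FALSE)
  structure(list(backbone = backbone, n_classes = n_classes,
                 pretrained = isTRUE(pretrained),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Mean cross-entropy cost
#'
#' Mean over samples of `-sum_i l_i log(l_hat_i)`; predicted probabilities
#' are floored at `1e-12` before the logarithm.
#'
#' @param probs `M x N` matrix of predicted probability rows.
#' @param targets `M x N` one-hot matrix, or an integer label vector of
#'   length `M` with values in `1..N`.
#' @return A nonnegative scalar.
#' @export
cross_entropy_cost <- function(probs, targets) {
  probs <- as.matrix(probs)
  if (!is.matrix(targets)) {
    lab <- as.integer(targets)
    targets <- matrix(0, length(lab), ncol(probs))
    targets[cbind(seq_along(lab), lab)] <- 1
  }
  if (!identical(dim(probs), dim(targets)))
    stop("`probs` and `targets` must have identical shapes", call. = FALSE)
  -sum(targets * log(pmax(probs, 1e-12))) / nrow(probs)
}

small_cnn_layers <- function(seed) {
  with_seed(seed, list(
    conv_layer(3L, 16L, 3L, 3L, 2L, 1L, "relu", sqrt(2 / (9 * 3))),
    conv_layer(16L, 32L, 3L, 3L, 2L, 1L, "relu", sqrt(2 / (9 * 16))),
    conv_layer(32L, 64L, 3L, 3L, 2L, 1L, "relu", sqrt(2 / (9 * 32)))))
}

small_cnn_forward <- function(layers, dense, xmat, H, W, B) {
  c1 <- conv_fwd(layers[[1L]], xmat, H, W, B)
  c2 <- conv_fwd(layers[[2L]], c1$a, c1$H, c1$W, B)
  c3 <- conv_fwd(layers[[3L]], c2$a, c2$H, c2$W, B)
  P <- c3$H * c3$W
  grp <- rep(seq_len(B), each = P)
  gap <- rowsum(c3$a, grp, reorder = FALSE) / P
  logits <- add_bias(gap %*% dense$W, dense$b)
  probs <- softmax_rows(logits)
  list(c1 = c1, c2 = c2, c3 = c3, gap = gap, probs = probs, P = P, grp = grp)
}

#' Fit the CNN classifier
#'
#' Minimizes the mean cross-entropy by Adam under `spec$seed`, with a
#' stratified validation hold-out and early stopping on validation loss
#' (best-epoch weights restored), mirroring the autoencoder's training
#' protocol.
#'
#' @param spec a [classifier_spec].
#' @param ds an [image_dataset] with at least two classes present; for the
#'   reference backbone both dimensions must be at least 8.
#' @return An object of class `fitted_classifier`.
#' @export
fit_classifier <- function(spec, ds) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(ds, "image_dataset"))
  if (spec$backbone != "reference_small_cnn")
    stop(sprintf(paste0("pretrained weights for backbone '%s' are not ",
                        "installed; only 'reference_small_cnn' is available"),
                 spec$backbone), call. = FALSE)
  if (length(unique(ds$labels)) < 2L)
    stop("training needs at least 2 classes present", call. = FALSE)
  if (img_height(ds) < 8L || img_width(ds) < 8L)
    stop("reference_small_cnn needs inputs of at least 8x8", call. = FALSE)
  split <- split_train_validation(ds, spec$validation_fraction,
                                  seed = spec$seed)
  H <- img_height(ds); W <- img_width(ds)
  N <- spec$n_classes
  layers <- small_cnn_layers(spec$seed)
  dense <- with_seed(spec$seed + 2L,
                     list(W = matrix(stats::rnorm(64L * N, sd = sqrt(1 / 64)),
                                     64L, N),
                          b = numeric(N)))
  n_train <- n_images(split$train)
  onehot <- function(lab) {
    m <- matrix(0, length(lab), N)
    m[cbind(seq_along(lab), lab)] <- 1
    m
  }
  eval_loss <- function(layers, dense, part) {
    f <- small_cnn_forward(layers, dense, as_feature_mat(part$images),
                           H, W, n_images(part))
    cross_entropy_cost(f$probs, part$labels)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, epoch = NA_integer_, layers = layers,
               dense = dense)
  with_seed(spec$seed + 1L, {
    params <- c(layer_params(layers), list(dense$W, dense$b))
    opt <- adam_init(params)
    t_step <- 0L
    bad <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      batch_losses <- numeric()
      for (idx in minibatches(n_train, spec$batch_size)) {
        B <- length(idx)
        xm <- as_feature_mat(split$train$images[, , , idx, drop = FALSE])
        f <- small_cnn_forward(layers, dense, xm, H, W, B)
        y <- onehot(split$train$labels[idx])
        batch_losses <- c(batch_losses, cross_entropy_cost(f$probs, y))
        dlogits <- (f$probs - y) / B
        dWd <- crossprod(f$gap, dlogits)
        dbd <- colSums(dlogits)
        dgap <- dlogits %*% t(dense$W)
        da3 <- dgap[f$grp, , drop = FALSE] / f$P
        g3 <- conv_bwd(layers[[3L]], f$c3, da3, f$c2$H, f$c2$W, B)
        g2 <- conv_bwd(layers[[2L]], f$c2, g3$dx, f$c1$H, f$c1$W, B)
        g1 <- conv_bwd(layers[[1L]], f$c1, g2$dx, H, W, B)
        t_step <- t_step + 1L
        upd <- adam_step(c(layer_params(layers), list(dense$W, dense$b)),
                         list(g1$dW, g1$db, g2$dW, g2$db, g3$dW, g3$db,
                              dWd, dbd),
                         opt, spec$learning_rate, t_step)
        opt <- upd$state
        layers <- set_layer_params(layers, upd$params[1:6])
        dense$W <- upd$params[[7L]]
        dense$b <- upd$params[[8L]]
      }
      val_loss <- eval_loss(layers, dense, split$validation)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(batch_losses),
                                  val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, epoch = epoch, layers = layers,
                     dense = dense)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= spec$patience) break
      }
    }
  })
  structure(list(spec = spec, layers = best$layers, dense = best$dense,
                 class_names = ds$class_names,
                 input_height = H, input_width = W,
                 training_history = history, best_epoch = best$epoch),
            class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat(sprintf("<fitted_classifier> %s, %d classes, input %dx%d, %d epochs\n",
              x$spec$backbone, x$spec$n_classes, x$input_height,
              x$input_width, nrow(x$training_history)))
  invisible(x)
}

#' Predict class probabilities
#'
#' Deterministic given the fitted weights; each row is a probability
#' vector over the classes (softmax output), and `max.col` of the result
#' is the predicted label used by the evaluation metrics.
#'
#' @param f a [fit_classifier()] result.
#' @param ds an [image_dataset] matching the fitted input size.
#' @return An `M x N` matrix of probabilities, columns named by class.
#' @export
predict_proba <- function(f, ds) {
  stopifnot(inherits(f, "fitted_classifier"))
  images <- if (inherits(ds, "image_dataset")) ds$images else ds
  d <- dim(images)
  if (d[1L] != f$input_height || d[2L] != f$input_width || d[3L] != 3L)
    stop(sprintf("input shape %dx%dx%d does not match the fitted %dx%dx3",
                 d[1L], d[2L], d[3L], f$input_height, f$input_width),
         call. = FALSE)
  M <- d[4L]
  probs <- matrix(0, M, f$spec$n_classes)
  chunk <- 128L
  for (s in seq(1L, M, by = chunk)) {
    idx <- s:min(s + chunk - 1L, M)
    fw <- small_cnn_forward(f$layers, f$dense,
                            as_feature_mat(images[, , , idx, drop = FALSE]),
                            f$input_height, f$input_width, length(idx))
    probs[idx, ] <- fw$probs
  }
  colnames(probs) <- f$class_names[seq_len(f$spec$n_classes)]
  probs
}
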