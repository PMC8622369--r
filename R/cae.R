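#' Convolutional autoencoder architecture
#'
#' The fixed symmetric four-layer topology: the encoder is
#' conv(4x4, 32 filters, stride 2) + ReLU followed by
#' conv(2x2, 3 filters, stride 2) + sigmoid, so an `H x W x 3` image is
#' compressed to an `H/4 x W/4 x 3` latent that is itself a valid RGB
#' image; the decoder mirrors the encoder with transposed convolutions
#' (2x2/32 then 4x4/3, both stride 2) and a sigmoid output, reconstructing
#' `H x W x 3` in \[0, 1\]. The first convolution uses symmetric padding 1
#' (4x4 kernel, stride 2 halves the size exactly) and the second padding 0;
#' the transposed layers mirror these so the decoder inverts the encoder's
#' shape algebra exactly.
#'
#' @param H,W input image size; both must be divisible by 4 and at least 4.
#' @param encoder_activation activation at the encoder output, `"sigmoid"`
#'   (default; latents are then images in \[0, 1\]) or `"relu"` (exposed
#'   for sensitivity checks).
#' @return An object of class `cae_architecture` with fields `H`, `W`,
#'   `latent_height = H/4`, `latent_width = W/4` and the four layer specs.
#' @export
build_cae <- function(H, W, encoder_activation = c("sigmoid", "relu")) {
  encoder_activation <- match.arg(encoder_activation)
  H <- as.integer(H); W <- as.integer(W)
  if (H %% 4L != 0L || W %% 4L != 0L || H < 4L || W < 4L)
    stop("`H` and `W` must be >= 4 and divisible by 4", call. = FALSE)
  layers <- list(
    enc1 = list(kind = "conv",   c_in = 3L,  c_out = 32L, kh = 4L, kw = 4L,
                stride = 2L, pad = 1L, act = "relu"),
    enc2 = list(kind = "conv",   c_in = 32L, c_out = 3L,  kh = 2L, kw = 2L,
                stride = 2L, pad = 0L, act = encoder_activation),
    dec1 = list(kind = "deconv", c_in = 3L,  c_out = 32L, kh = 2L, kw = 2L,
                stride = 2L, pad = 0L, act = "relu"),
    dec2 = list(kind = "deconv", c_in = 32L, c_out = 3L,  kh = 4L, kw = 4L,
                stride = 2L, pad = 1L, act = "sigmoid"))
  structure(list(H = H, W = W, latent_height = H %/% 4L,
                 latent_width = W %/% 4L, layers = layers),
            class = "cae_architecture")
}

#' @export
print.cae_architecture <- function(x, ...) {
  cat(sprintf("<cae_architecture> %dx%dx3 -> latent %dx%dx3 -> %dx%dx3\n",
              x$H, x$W, x$latent_height, x$latent_width, x$H, x$W))
  invisible(x)
}

materialize_layer <- function(spec) {
  init_sd <- sqrt(1 / (spec$kh * spec$kw * spec$c_in))
  if (spec$kind == "conv") {
    conv_layer(spec$c_in, spec$c_out, spec$kh, spec$kw, spec$stride,
               spec$pad, spec$act, init_sd)
  } else {
    deconv_layer(spec$c_in, spec$c_out, spec$kh, spec$kw, spec$stride,
                 spec$pad, spec$act, init_sd)
  }
}

#' Initialize an (untrained) CAE model
#'
#' Random fan-in-scaled weights under `seed`; mostly useful for shape
#' checks and as the starting point of [train_cae()].
#'
#' @param architecture a [build_cae()] architecture.
#' @param seed integer seed for the weight draw.
#' @return An object of class `cae_model`.
#' @export
init_cae <- function(architecture, seed = 1L) {
  stopifnot(inherits(architecture, "cae_architecture"))
  layers <- with_seed(seed, lapply(architecture$layers, materialize_layer))
  structure(list(architecture = architecture, layers = layers,
                 training_history = data.frame(epoch = integer(),
                                               train_loss = numeric(),
                                               val_loss = numeric()),
                 best_epoch = NA_integer_),
            class = "cae_model")
}

#' @export
print.cae_model <- function(x, ...) {
  print(x$architecture)
  if (nrow(x$training_history) > 0L)
    cat(sprintf("  trained %d epochs, best epoch %d (val loss %.6g)\n",
                nrow(x$training_history), x$best_epoch,
                x$training_history$val_loss[x$best_epoch]))
  else cat("  untrained\n")
  invisible(x)
}

cae_forward_enc <- function(model, xmat, B) {
  a <- model$architecture
  c1 <- conv_fwd(model$layers$enc1, xmat, a$H, a$W, B)
  c2 <- conv_fwd(model$layers$enc2, c1$a, c1$H, c1$W, B)
  list(c1 = c1, c2 = c2)
}

cae_forward_dec <- function(model, ymat, B) {
  a <- model$architecture
  d1 <- deconv_fwd(model$layers$dec1, ymat, a$latent_height, a$latent_width, B)
  d2 <- deconv_fwd(model$layers$dec2, d1$a, d1$H, d1$W, B)
  list(d1 = d1, d2 = d2)
}

check_cae_input <- function(model, images, what = "input") {
  d <- dim(images)
  a <- model$architecture
  if (d[1L] != a$H || d[2L] != a$W || d[3L] != 3L)
    stop(sprintf("%s shape %dx%dx%d does not match the architecture (%dx%dx3)",
                 what, d[1L], d[2L], d[3L], a$H, a$W), call. = FALSE)
}

# run a dataset through fn(images_chunk) in memory-bounded chunks
chunked_map <- function(images, fn, chunk = 64L) {
  M <- dim(images)[4L]
  out <- NULL
  for (s in seq(1L, M, by = chunk)) {
    idx <- s:min(s + chunk - 1L, M)
    res <- fn(images[, , , idx, drop = FALSE], length(idx))
    if (is.null(out)) {
      d <- dim(res)
      out <- array(0, c(d[1:3], M))
    }
    out[, , , idx] <- res
    }
  out
}

#' Encode a dataset to its compressed latent representation
#'
#' Deterministic given the model weights. The latent is an
#' `H/4 x W/4 x 3` image in \[0, 1\] (sigmoid output), so the result is
#' itself a valid [image_dataset] — labels are carried through — that can
#' feed any classifier or be written as PNG.
#'
#' @param model a `cae_model` (see [init_cae()], [train_cae()]).
#' @param x an [image_dataset] (or bare `H x W x 3 x M` array) matching the
#'   architecture's input size.
#' @return The encoded [image_dataset] (or array, if `x` was an array).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "cae_model"))
  images <- if (inherits(x, "image_dataset")) x$images else x
  check_cae_input(model, images)
  a <- model$architecture
  out <- chunked_map(images, function(chunk, B) {
    f <- cae_forward_enc(model, as_feature_mat(chunk), B)
    feature_mat_to_array(f$c2$a, a$latent_height, a$latent_width, 3L, B)
  })
  if (inherits(x, "image_dataset"))
    image_dataset(out, x$labels, x$class_names)
  else out
}

#' Decode a latent dataset back to image space
#'
#' Mirror of [encode()]: maps `H/4 x W/4 x 3` latents to `H x W x 3`
#' reconstructions in \[0, 1\].
#'
#' @param model a `cae_model` (see [init_cae()], [train_cae()]).
#' @param y encoded [image_dataset] (or array) of size `H/4 x W/4 x 3 x M`.
#' @return The reconstructed [image_dataset] (or array).
#' @export
decode <- function(model, y) {
  stopifnot(inherits(model, "cae_model"))
  images <- if (inherits(y, "image_dataset")) y$images else y
  d <- dim(images)
  a <- model$architecture
  if (d[1L] != a$latent_height || d[2L] != a$latent_width || d[3L] != 3L)
    stop(sprintf("latent shape %dx%dx%d does not match %dx%dx3",
                 d[1L], d[2L], d[3L], a$latent_height, a$latent_width),
         call. = FALSE)
  out <- chunked_map(images, function(chunk, B) {
    f <- cae_forward_dec(model, as_feature_mat(chunk), B)
    feature_mat_to_array(f$d2$a, a$H, a$W, 3L, B)
  })
  if (inherits(y, "image_dataset"))
    image_dataset(out, y$labels, y$class_names)
  else out
}

#' Mean reconstruction loss
#'
#' The training objective of the autoencoder: the batch mean of the squared
#' Euclidean distance `0.5 * ||x_hat - x||^2` summed over all pixels and
#' channels of each sample.
#'
#' @param x_hat,x image batches of identical shape (`H x W x 3 x M` arrays
#'   or [image_dataset]s).
#' @return A nonnegative scalar.
#' @export
reconstruction_loss <- function(x_hat, x) {
  a <- if (inherits(x_hat, "image_dataset")) x_hat$images else x_hat
  b <- if (inherits(x, "image_dataset")) x$images else x
  if (!identical(dim(a), dim(b)))
    stop("`x_hat` and `x` must have identical shapes", call. = FALSE)
  d <- dim(a)
  M <- if (length(d) == 4L) d[4L] else 1L
  0.5 * sum((a - b)^2) / M
}

#' Training settings for the autoencoder
#'
#' Adam at learning rate `1e-3` is the prescribed optimizer; batch size,
#' epoch cap and early-stopping patience are free knobs with conventional
#' defaults.
#'
#' @param learning_rate Adam step size (default `1e-3`).
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience: training stops once the
#'   validation loss has not improved for this many consecutive epochs.
#' @param validation_fraction fraction of the data held out (stratified)
#'   for validation-loss early stopping; default 10%.
#' @param seed controls the validation split, weight initialization and
#'   minibatch order.
#' @return An object of class `cae_train_settings`.
#' @export
cae_train_settings <- function(learning_rate = 1e-3, batch_size = 32L,
                               max_epochs = 100L, patience = 10L,
                               validation_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 1L, batch_size >= 1L,
            max_epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "cae_train_settings")
}

cae_eval_loss <- function(model, images, chunk = 64L) {
  M <- dim(images)[4L]
  total <- 0
  for (s in seq(1L, M, by = chunk)) {
    idx <- s:min(s + chunk - 1L, M)
    B <- length(idx)
    xm <- as_feature_mat(images[, , , idx, drop = FALSE])
    enc <- cae_forward_enc(model, xm, B)
    dec <- cae_forward_dec(model, enc$c2$a, B)
    total <- total + 0.5 * sum((dec$d2$a - xm)^2)
  }
  total / M
}

#' Train the convolutional autoencoder
#'
#' Minimizes the mean reconstruction loss by Adam. A stratified 10% of the
#' data (seeded) is held out; after every epoch the validation loss is
#' evaluated and training stops once it has not improved for
#' `settings$patience` consecutive epochs (or at `max_epochs`). The weights
#' returned are those of the best-validation epoch, so the best validation
#' loss over training never exceeds the epoch-1 validation loss.
#'
#' @param ds an [image_dataset] whose images match a 4-divisible size.
#' @param settings a [cae_train_settings].
#' @return A trained `cae_model`; `$training_history` holds the per-epoch
#'   train/validation losses and `$best_epoch` the restored epoch.
#' @export
train_cae <- function(ds, settings = cae_train_settings()) {
  stopifnot(inherits(ds, "image_dataset"),
            inherits(settings, "cae_train_settings"))
  if (n_images(ds) < 2L)
    stop("training needs at least 2 samples", call. = FALSE)
  if (img_height(ds) %% 4L != 0L || img_width(ds) %% 4L != 0L)
    stop("image size must be divisible by 4", call. = FALSE)
  split <- split_train_validation(ds, settings$validation_fraction,
                                  seed = settings$seed)
  arch <- build_cae(img_height(ds), img_width(ds))
  model <- init_cae(arch, seed = settings$seed)
  n_train <- n_images(split$train)

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, epoch = NA_integer_, layers = model$layers)
  with_seed(settings$seed + 1L, {
    opt <- adam_init(layer_params(model$layers))
    t_step <- 0L
    bad <- 0L
    for (epoch in seq_len(settings$max_epochs)) {
      batch_losses <- numeric()
      for (idx in minibatches(n_train, settings$batch_size)) {
        B <- length(idx)
        xm <- as_feature_mat(split$train$images[, , , idx, drop = FALSE])
        enc <- cae_forward_enc(model, xm, B)
        dec <- cae_forward_dec(model, enc$c2$a, B)
        loss <- 0.5 * sum((dec$d2$a - xm)^2) / B
        batch_losses <- c(batch_losses, loss)
        dxhat <- (dec$d2$a - xm) / B
        g4 <- deconv_bwd(model$layers$dec2, dec$d2, dxhat, B)
        g3 <- deconv_bwd(model$layers$dec1, dec$d1, g4$dx, B)
        g2 <- conv_bwd(model$layers$enc2, enc$c2, g3$dx, enc$c1$H, enc$c1$W, B)
        g1 <- conv_bwd(model$layers$enc1, enc$c1, g2$dx,
                       arch$H, arch$W, B)
        t_step <- t_step + 1L
        upd <- adam_step(layer_params(model$layers),
                         list(g1$dW, g1$db, g2$dW, g2$db,
                              g3$dW, g3$db, g4$dW, g4$db),
                         opt, settings$learning_rate, t_step)
        opt <- upd$state
        model$layers <- set_layer_params(model$layers, upd$params)
      }
      val_loss <- cae_eval_loss(model, split$validation$images)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(batch_losses),
                                  val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, epoch = epoch, layers = model$layers)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= settings$patience) break
      }
    }
  })
  model$layers <- best$layers
  model$training_history <- history
  model$best_epoch <- best$epoch
  model
}
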