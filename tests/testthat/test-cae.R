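test_that("the architecture compresses to exactly H/4 x W/4 x 3", {
  a <- build_cae(1024, 1024)
  expect_equal(c(a$latent_height, a$latent_width), c(256, 256))
  a <- build_cae(600, 600)
  expect_equal(c(a$latent_height, a$latent_width), c(150, 150))
  a <- build_cae(4, 4)
  expect_equal(c(a$latent_height, a$latent_width), c(1, 1))
  expect_error(build_cae(30, 32), "divisible by 4")
  # decoder mirrors the encoder kernel/filter sequence
  expect_equal(a$layers$dec1$kh, a$layers$enc2$kh)
  expect_equal(a$layers$dec2$kh, a$layers$enc1$kh)
  expect_equal(a$layers$dec1$c_out, a$layers$enc1$c_out)
})

test_that("encode/decode satisfy the shape and range contracts untrained", {
  model <- init_cae(build_cae(16, 24), seed = 8)
  x <- array(runif(16 * 24 * 3 * 5), c(16, 24, 3, 5))
  y <- encode(model, x)
  expect_equal(dim(y), c(4, 6, 3, 5))
  expect_true(all(y >= 0 & y <= 1))
  xr <- decode(model, y)
  expect_equal(dim(xr), c(16, 24, 3, 5))
  expect_true(all(xr >= 0 & xr <= 1))
  expect_identical(encode(model, x), y)    # deterministic given weights
  expect_error(encode(model, array(0, c(8, 8, 3, 1))), "does not match")
  expect_error(decode(model, array(0, c(8, 8, 3, 1))), "does not match")
})

test_that("encode carries labels so latents feed classifiers directly", {
  ds <- generate_dataset(tiny_spec())
  model <- init_cae(build_cae(16, 16), seed = 1)
  y <- encode(model, ds)
  expect_s3_class(y, "image_dataset")
  expect_identical(y$labels, ds$labels)
  expect_identical(y$class_names, ds$class_names)
  expect_equal(dim(y$images)[1:2], c(4, 4))
})

test_that("reconstruction loss matches brute-force evaluation", {
  expect_equal(reconstruction_loss(array(1, c(2, 2, 3, 4)),
                                   array(1, c(2, 2, 3, 4))), 0)
  # single flattened sample: 0.5 * ((1-0)^2 + (0-1)^2) = 1
  expect_equal(reconstruction_loss(c(1, 0, 0), c(0, 1, 0)), 1.0)
  # batch mean of per-sample losses 1 and 3 is 2
  xh <- array(0, c(1, 1, 3, 2)); x <- array(0, c(1, 1, 3, 2))
  xh[1, 1, , 1] <- c(1, 1, 0); x[1, 1, , 1] <- c(0, 0, 0)    # 0.5*2 = 1
  xh[1, 1, , 2] <- c(2, 1, 1); x[1, 1, , 2] <- c(0, 0, 0)    # 0.5*6 = 3
  expect_equal(reconstruction_loss(xh, x), 2.0)
  # brute force elementwise oracle on random batches
  set.seed(31)
  for (rep in 1:3) {
    a <- array(runif(4 * 4 * 3 * 3), c(4, 4, 3, 3))
    b <- array(runif(4 * 4 * 3 * 3), c(4, 4, 3, 3))
    manual <- mean(vapply(1:3, function(k)
      0.5 * sum((a[, , , k] - b[, , , k])^2), numeric(1)))
    expect_equal(reconstruction_loss(a, b), manual, tolerance = 1e-10)
  }
  expect_error(reconstruction_loss(array(0, c(2, 2, 3, 1)),
                                   array(0, c(4, 4, 3, 1))), "identical shapes")
})

test_that("a constant all-zero target is learned to near zero loss", {
  ds <- image_dataset(array(0, c(8, 8, 3, 32)), rep(1L, 32), "zero")
  m <- train_cae(ds, cae_train_settings(batch_size = 2, max_epochs = 30,
                                        patience = 30, seed = 5))
  h <- m$training_history
  expect_lt(tail(h$train_loss, 1), 0.1 * h$train_loss[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- generate_dataset(tiny_spec())
  st <- cae_train_settings(max_epochs = 3, seed = 12)
  m1 <- train_cae(ds, st)
  m2 <- train_cae(ds, st)
  expect_identical(m1$training_history, m2$training_history)
  expect_identical(m1$layers, m2$layers)
})

test_that("early stopping keeps the best epoch and stops after patience", {
  # a deliberately unstable learning rate makes the validation loss rise
  ds <- generate_dataset(synthetic_spec(2, 10, 16, 16, noise_sigma = 0.3,
                                        seed = 2))
  m <- train_cae(ds, cae_train_settings(learning_rate = 0.5, max_epochs = 30,
                                        patience = 1, seed = 2))
  h <- m$training_history
  expect_equal(nrow(h), 2)                       # stops right after epoch 1
  expect_equal(m$best_epoch, which.min(h$val_loss))
  expect_gte(h$val_loss[2], h$val_loss[1])
  # weak monotonicity: best val loss never exceeds the epoch-1 val loss
  ds2 <- generate_dataset(tiny_spec())
  m2 <- train_cae(ds2, cae_train_settings(max_epochs = 5, seed = 3))
  expect_lte(min(m2$training_history$val_loss),
             m2$training_history$val_loss[1])
})

test_that("a trained autoencoder denoises toward the clean patterns", {
  # small-scale filtering check; the full-scale claim is exercised in the
  # acceptance suite
  sp <- synthetic_spec(3, 30, 32, 32, signal_amplitude = 0.5,
                       noise_sigma = 0.2, clutter_amplitude = 0.2, seed = 6)
  ds <- generate_dataset(sp)
  clean <- array(0, dim(ds$images))
  pats <- lapply(1:3, make_class_pattern, spec = sp)
  for (k in seq_len(90)) clean[, , , k] <- pats[[ds$labels[k]]]
  m <- train_cae(ds, cae_train_settings(max_epochs = 10, patience = 10,
                                        seed = 6))
  recon <- decode(m, encode(m, ds))
  expect_lt(mean((recon$images - clean)^2), mean((ds$images - clean)^2))
})
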