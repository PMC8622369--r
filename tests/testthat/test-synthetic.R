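test_that("class patterns are deterministic, bounded and class-discriminative", {
  sp <- synthetic_spec(n_classes = 3, samples_per_class = 1, height = 64,
                       width = 64, signal_amplitude = 0.5, seed = 7)
  p1a <- make_class_pattern(1, sp)
  p1b <- make_class_pattern(1, sp)
  expect_identical(p1a, p1b)
  expect_true(all(p1a >= 0 & p1a <= 1))
  p2 <- make_class_pattern(2, sp)
  # regression value computed once from this generator
  expect_equal(mean(abs(p1a - p2)), 0.0746494, tolerance = 1e-6)
  expect_gt(mean(abs(p1a - p2)), 0)
  expect_error(make_class_pattern(4, sp), "class_index")
})

test_that("zero signal amplitude gives mid-gray patterns for every class", {
  sp <- synthetic_spec(n_classes = 3, samples_per_class = 1, height = 16,
                       width = 16, signal_amplitude = 0, seed = 3)
  for (cl in 1:3)
    expect_equal(make_class_pattern(cl, sp),
                 array(0.5, c(16, 16, 3)))
})

test_that("generated datasets are balanced, clipped and seed-reproducible", {
  sp <- synthetic_spec(n_classes = 3, samples_per_class = 20, height = 16,
                       width = 16, noise_sigma = 0.3, sp_fraction = 0.02,
                       noise_model = "mixed", seed = 9)
  ds <- generate_dataset(sp)
  expect_equal(dim(ds$images), c(16, 16, 3, 60))
  expect_equal(tabulate(ds$labels), c(20, 20, 20))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  expect_identical(ds, generate_dataset(sp))
  expect_error(synthetic_spec(height = 18, width = 16), "divisible by 4")
})

test_that("the noiseless limit reproduces the class patterns exactly", {
  sp <- synthetic_spec(n_classes = 3, samples_per_class = 4, height = 16,
                       width = 16, noise_sigma = 0, sp_fraction = 0,
                       clutter_amplitude = 0, seed = 5)
  ds <- generate_dataset(sp)
  for (k in seq_len(12))
    expect_equal(ds$images[, , , k], make_class_pattern(ds$labels[k], sp))
})

test_that("additive gaussian noise has the configured standard deviation", {
  # flat mid-gray patterns, sigma far from the clip boundaries
  sp <- synthetic_spec(n_classes = 1, samples_per_class = 30, height = 64,
                       width = 64, signal_amplitude = 0, noise_sigma = 0.1,
                       clutter_amplitude = 0, seed = 21)
  ds <- generate_dataset(sp)
  resid <- ds$images - 0.5            # > 1e5 pixels
  expect_equal(stats::sd(resid), 0.1, tolerance = 0.005)
})

test_that("salt-and-pepper replaces the configured pixel fraction", {
  sp <- synthetic_spec(n_classes = 1, samples_per_class = 10, height = 32,
                       width = 32, signal_amplitude = 0, noise_sigma = 0,
                       clutter_amplitude = 0, noise_model = "salt_pepper",
                       sp_fraction = 0.1, seed = 4)
  ds <- generate_dataset(sp)
  frac <- mean(ds$images[, , 1, ] %in% c(0, 1))
  expect_equal(frac, round(0.1 * 32 * 32) / (32 * 32), tolerance = 1e-9)
})

test_that("noise seeds vary the samples but not the class distributions", {
  sp <- tiny_spec()
  a <- generate_dataset(sp)
  b <- generate_dataset(sp, noise_seed = 999L)
  expect_false(identical(a$images, b$images))
  # same clean patterns underneath
  expect_identical(make_class_pattern(1, sp), make_class_pattern(1, sp))
})

test_that("nearest-centroid accuracy is perfect when clean and degrades with noise", {
  base <- synthetic_spec(n_classes = 3, samples_per_class = 12, height = 32,
                         width = 32, signal_amplitude = 0.5,
                         clutter_amplitude = 0, seed = 17)
  centroids <- lapply(1:3, make_class_pattern, spec = base)
  nc_accuracy <- function(ds) {
    pred <- vapply(seq_len(dim(ds$images)[4]), function(k) {
      d <- vapply(centroids, function(ce)
        sum((ds$images[, , , k] - ce)^2), numeric(1))
      which.min(d)
    }, integer(1))
    mean(pred == ds$labels)
  }
  sigmas <- c(0, 0.3, 0.8, 2.0)
  acc <- vapply(sigmas, function(s) {
    # average over 5 noise seeds at each level
    mean(vapply(1:5, function(rep) {
      sp <- base; sp$noise_sigma <- s
      nc_accuracy(generate_dataset(sp, noise_seed = 1000L + rep))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 0.02))   # monotone within sampling error
  expect_lt(acc[4], acc[1])
})
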