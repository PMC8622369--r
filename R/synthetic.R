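#' Specification for a synthetic noisy image dataset
#'
#' Describes a labeled image dataset with the statistical structure the
#' CAE-CNN pipeline targets: class-discriminative low-spatial-frequency
#' signal (seeded Gaussian bumps, 2-4 per class), redundant high-frequency
#' clutter whose distribution is identical across classes (random
#' sinusoidal texture), and heavy pixel noise. All intensities live on the
#' \[0, 1\] scale; images are clipped after noise addition so they remain
#' storable as 8-bit PNG.
#'
#' @param n_classes number of classes.
#' @param samples_per_class images generated per class.
#' @param height,width image size in pixels; both must be divisible by 4
#'   (the encoder halves the resolution twice).
#' @param signal_amplitude peak-to-trough amplitude of the class signal on
#'   the intensity scale, in (0, 1\]; `0` is accepted and yields
#'   mid-gray patterns for every class.
#' @param noise_model `"gaussian"` (additive, sd `noise_sigma`),
#'   `"salt_pepper"` (a fraction `sp_fraction` of pixels replaced by 0 or
#'   1), or `"mixed"` (both).
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param sp_fraction fraction of pixels replaced by salt/pepper, in
#'   \[0, 1\].
#' @param clutter_amplitude amplitude of the shared high-frequency texture.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   dataset.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, samples_per_class = 100L,
                           height = 64L, width = 64L,
                           signal_amplitude = 0.5,
                           noise_model = c("gaussian", "salt_pepper", "mixed"),
                           noise_sigma = 0.2, sp_fraction = 0.05,
                           clutter_amplitude = 0.2, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (height %% 4L != 0L || width %% 4L != 0L)
    stop("`height` and `width` must be divisible by 4", call. = FALSE)
  if (n_classes < 1L || samples_per_class < 1L)
    stop("`n_classes` and `samples_per_class` must be positive", call. = FALSE)
  if (signal_amplitude < 0 || signal_amplitude > 1)
    stop("`signal_amplitude` must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0 || sp_fraction < 0 || sp_fraction > 1 ||
      clutter_amplitude < 0)
    stop("invalid noise parameters", call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 height = as.integer(height), width = as.integer(width),
                 signal_amplitude = signal_amplitude,
                 noise_model = noise_model, noise_sigma = noise_sigma,
                 sp_fraction = sp_fraction,
                 clutter_amplitude = clutter_amplitude,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# per-class bump parameters, a pure function of spec$seed
class_pattern_params <- function(spec) {
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_classes), function(cl) {
      n_bumps <- sample(2:4, 1L)
      list(n_bumps = n_bumps,
           cx = stats::runif(n_bumps, 0.15, 0.85),
           cy = stats::runif(n_bumps, 0.15, 0.85),
           sigma = stats::runif(n_bumps, 0.10, 0.22),
           # signed per-channel weights: which channels a bump lives in
           wts = matrix(stats::runif(3L * n_bumps, -1, 1), 3L, n_bumps))
    })
  })
}

#' Clean class pattern
#'
#' The deterministic noise-free image of one class: mid-gray plus
#' `signal_amplitude` times a smooth field built from that class's seeded
#' Gaussian bumps. Smoothness is deliberate — the signal must survive the
#' encoder's 4x downsampling.
#'
#' @param class_index class index in `1..n_classes`.
#' @param spec a [synthetic_spec].
#' @return An `H x W x 3` array with values in \[0, 1\].
#' @export
make_class_pattern <- function(class_index, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (class_index < 1L || class_index > spec$n_classes)
    stop("`class_index` must lie in 1..n_classes", call. = FALSE)
  p <- class_pattern_params(spec)[[class_index]]
  H <- spec$height; W <- spec$width
  ry <- (seq_len(H) - 0.5) / H
  rx <- (seq_len(W) - 0.5) / W
  img <- array(0, c(H, W, 3L))
  for (b in seq_len(p$n_bumps)) {
    g <- exp(-(outer((ry - p$cy[b])^2, (rx - p$cx[b])^2, "+")) /
               (2 * p$sigma[b]^2))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + p$wts[ch, b] * g
  }
  img <- pmin(pmax(img, -1), 1)
  0.5 + 0.5 * spec$signal_amplitude * img
}

# shared high-frequency clutter texture; parameters drawn from the current
# RNG stream so each sample gets a fresh field with a class-independent
# distribution
clutter_field <- function(H, W, n_waves = 3L) {
  ry <- seq_len(H) - 0.5
  rx <- seq_len(W) - 0.5
  f <- matrix(0, H, W)
  for (i in seq_len(n_waves)) {
    freq <- stats::runif(1L, 0.25, 0.45)      # cycles per pixel: high freq.
    theta <- stats::runif(1L, 0, pi)
    phase <- stats::runif(1L, 0, 2 * pi)
    f <- f + sin(2 * pi * freq * (outer(ry * cos(theta), rx * sin(theta), "+")) +
                   phase)
  }
  f / n_waves
}

#' Generate a synthetic labeled noisy image dataset
#'
#' Each sample is its class pattern plus a freshly drawn clutter field and
#' pixel noise per `spec$noise_model`, clipped to \[0, 1\]. Classes are
#' perfectly balanced; samples are ordered class-major. Identical
#' spec + seed reproduce the dataset bit for bit.
#'
#' @param spec a [synthetic_spec].
#' @param noise_seed seed of the clutter/noise stream only; the class
#'   patterns always derive from `spec$seed`, so two calls with different
#'   `noise_seed` give disjoint samples from the same class distributions
#'   (e.g. a train/test pair).
#' @return An [image_dataset] with `n_classes * samples_per_class` images.
#' @export
generate_dataset <- function(spec, noise_seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$height; W <- spec$width
  M <- spec$n_classes * spec$samples_per_class
  patterns <- lapply(seq_len(spec$n_classes), make_class_pattern, spec = spec)
  images <- array(0, c(H, W, 3L, M))
  labels <- rep(seq_len(spec$n_classes), each = spec$samples_per_class)
  with_seed(as.integer(noise_seed), {
    for (k in seq_len(M)) {
      img <- patterns[[labels[k]]]
      # clutter draws are consumed even at amplitude 0 so the noise stream
      # lines up across clutter settings
      cf <- clutter_field(H, W)
      if (spec$clutter_amplitude > 0)
        img <- img + spec$clutter_amplitude * array(cf, c(H, W, 3L))
      if (spec$noise_model %in% c("gaussian", "mixed") && spec$noise_sigma > 0)
        img <- img + array(stats::rnorm(H * W * 3L, sd = spec$noise_sigma),
                           c(H, W, 3L))
      if (spec$noise_model %in% c("salt_pepper", "mixed") &&
          spec$sp_fraction > 0) {
        n_px <- H * W
        n_sp <- round(spec$sp_fraction * n_px)
        if (n_sp > 0L) {
          px <- sample.int(n_px, n_sp)
          val <- sample(c(0, 1), n_sp, replace = TRUE)
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[px] <- val
            img[, , ch] <- plane
          }
        }
      }
      images[, , , k] <- pmin(pmax(img, 0), 1)
    }
  })
  image_dataset(images, labels,
                sprintf("class%02d", seq_len(spec$n_classes)))
}

#' Write an image dataset as a class-folder PNG tree
#'
#' Emits `root/<class_name>/<index>.png` (8-bit RGB) plus a
#' `manifest.json` recording the class names, per-file MD5 checksums and,
#' when the dataset came from [generate_dataset()], the generating spec.
#'
#' @param ds an [image_dataset].
#' @param root output directory (created if absent).
#' @param spec optional [synthetic_spec] echoed into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_image_dataset <- function(ds, root, spec = NULL) {
  stopifnot(inherits(ds, "image_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  files <- character(n_images(ds))
  counter <- integer(length(ds$class_names))
  for (k in seq_len(n_images(ds))) {
    cl <- ds$labels[k]
    dir.create(file.path(root, ds$class_names[cl]), showWarnings = FALSE)
    counter[cl] <- counter[cl] + 1L
    files[k] <- file.path(root, ds$class_names[cl],
                          sprintf("%04d.png", counter[cl]))
    png::writePNG(ds$images[, , , k], files[k])
  }
  manifest <- list(class_names = ds$class_names,
                   n_images = n_images(ds),
                   height = img_height(ds), width = img_width(ds),
                   checksums = as.list(stats::setNames(
                     unname(tools::md5sum(files)),
                     substring(files, nchar(root) + 2L))))
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  manifest_path <- file.path(root, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
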