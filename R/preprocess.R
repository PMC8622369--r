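#' Preprocessing approaches
#'
#' The three interchangeable dataset transforms the pipeline compares:
#'
#' * **traditional** — the identity: raw images go straight to the
#'   classifier.
#' * **md** — non-local means denoising ([nlm_denoise()]) applied image by
#'   image; output keeps the input size.
#' * **cae** — compression through a trained autoencoder's encoder
#'   ([encode()]); output is `H/4 x W/4 x 3`.
#'
#' All three preserve the sample count, the labels and the \[0, 1\] range.
#'
#' @param patch_radius,search_radius,h,sigma non-local means parameters,
#'   see [nlm_denoise()].
#' @param model a trained `cae_model` ([train_cae()]) for the cae arm.
#' @return An object of class `approach`.
#' @name approaches
NULL

#' @rdname approaches
#' @export
traditional_approach <- function() {
  structure(list(name = "traditional"), class = "approach")
}

#' @rdname approaches
#' @export
md_approach <- function(patch_radius = 1L, search_radius = 5L, h = 0.1,
                        sigma = NULL) {
  structure(list(name = "md", patch_radius = as.integer(patch_radius),
                 search_radius = as.integer(search_radius), h = h,
                 sigma = sigma),
            class = "approach")
}

#' @rdname approaches
#' @export
cae_approach <- function(model = NULL) {
  structure(list(name = "cae", model = model), class = "approach")
}

#' @export
print.approach <- function(x, ...) {
  cat("<approach>", x$name, "\n")
  invisible(x)
}

#' Apply a preprocessing approach to a dataset
#'
#' @param a an [approaches] object.
#' @param ds an [image_dataset]; for the cae arm its size must match the
#'   model's architecture.
#' @return The transformed [image_dataset]; labels pass through unchanged.
#' @export
apply_approach <- function(a, ds) {
  stopifnot(inherits(a, "approach"), inherits(ds, "image_dataset"))
  switch(a$name,
    traditional = ds,
    md = {
      out <- ds$images
      for (k in seq_len(n_images(ds)))
        out[, , , k] <- nlm_denoise(ds$images[, , , k], a$patch_radius,
                                    a$search_radius, a$h, a$sigma)
      image_dataset(out, ds$labels, ds$class_names)
    },
    cae = {
      if (is.null(a$model) || !inherits(a$model, "cae_model"))
        stop("the cae approach needs a trained `cae_model`", call. = FALSE)
      encode(a$model, ds)
    },
    stop("unknown approach: ", a$name))
}

# robust noise-level estimate from horizontal first differences:
# sd = MAD(diff) / (0.6745 * sqrt(2))
estimate_noise_sd <- function(channel) {
  d <- channel[, -1L, drop = FALSE] - channel[, -ncol(channel), drop = FALSE]
  stats::median(abs(d - stats::median(d))) / (0.6745 * sqrt(2))
}

#' Non-local means denoising
#'
#' Each output pixel is the weight-normalized average of the pixels in its
#' `(2*search_radius+1)^2` search window; the weight of a candidate pixel
#' is `exp(-max(d2 - 2*sigma^2, 0)/h^2)` where `d2` is the mean squared
#' difference between the `(2*patch_radius+1)^2` patches around the two
#' pixels. Channels are processed independently; `sigma` (the assumed
#' noise standard deviation) is estimated per channel from the median
#' absolute horizontal pixel difference when not supplied. With
#' `search_radius = 0` only the pixel itself contributes and the image is
#' returned unchanged.
#'
#' @param img an `H x W x 3` array (or `H x W` matrix) in \[0, 1\].
#' @param patch_radius patch half-width (default 1, i.e. 3x3 patches).
#' @param search_radius search-window half-width (default 5, 11x11 window).
#' @param h filtering strength on the intensity scale (default 0.1).
#' @param sigma optional noise sd; estimated when `NULL`.
#' @return The denoised image, clipped to \[0, 1\].
#' @export
nlm_denoise <- function(img, patch_radius = 1L, search_radius = 5L,
                        h = 0.1, sigma = NULL) {
  if (patch_radius < 0L || search_radius < 0L || h <= 0)
    stop("radii must be >= 0 and `h` > 0", call. = FALSE)
  two_d <- length(dim(img)) == 2L
  if (two_d) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  if (2L * patch_radius + 1L > min(d[1L], d[2L]))
    stop("patch larger than the image", call. = FALSE)
  out <- img
  for (ch in seq_len(d[3L])) {
    plane <- img[, , ch]
    s <- if (is.null(sigma)) estimate_noise_sd(plane) else sigma
    res <- .nlm_channel_cpp(as.numeric(plane), d[1L], d[2L],
                            as.integer(patch_radius),
                            as.integer(search_radius), h, s)
    out[, , ch] <- pmin(pmax(matrix(res, d[1L], d[2L]), 0), 1)
  }
  if (two_d) out[, , 1L] else out
}
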