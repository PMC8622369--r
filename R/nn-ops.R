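# Internal minimal neural-network engine.
#
# Feature maps travel as (H*W*B) x C matrices with row index
# h + H*w + H*W*b (see src/convops.cpp); convolutions are im2col gathers
# followed by BLAS matrix products, transposed convolutions are the exact
# adjoint (col2im scatter-add), so encoder/decoder shapes invert exactly.

as_feature_mat <- function(images) {
  d <- dim(images)
  x <- aperm(images, c(1L, 2L, 4L, 3L))
  dim(x) <- c(d[1L] * d[2L] * d[4L], d[3L])
  x
}

feature_mat_to_array <- function(x, H, W, C, B) {
  dim(x) <- c(H, W, B, C)
  aperm(x, c(1L, 2L, 4L, 3L))
}

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

relu_fwd <- function(z) (z > 0) * z
sigmoid_fwd <- function(z) 1 / (1 + exp(-z))

act_fwd <- function(z, act) {
  switch(act, relu = relu_fwd(z), sigmoid = sigmoid_fwd(z), linear = z,
         stop("unknown activation: ", act))
}

# derivative expressed through the activation output a (= act(z))
act_bwd <- function(da, a, act) {
  switch(act, relu = da * (a > 0), sigmoid = da * a * (1 - a), linear = da,
         stop("unknown activation: ", act))
}

add_bias <- function(z, b) {
  for (j in seq_along(b)) z[, j] <- z[, j] + b[j]
  z
}

conv_layer <- function(c_in, c_out, kh, kw, stride, pad, act, init_sd) {
  list(type = "conv", c_in = c_in, c_out = c_out, kh = kh, kw = kw,
       stride = stride, pad = pad, act = act,
       W = matrix(stats::rnorm(kh * kw * c_in * c_out, sd = init_sd),
                  kh * kw * c_in, c_out),
       b = numeric(c_out))
}

deconv_layer <- function(c_in, c_out, kh, kw, stride, pad, act, init_sd) {
  list(type = "deconv", c_in = c_in, c_out = c_out, kh = kh, kw = kw,
       stride = stride, pad = pad, act = act,
       W = matrix(stats::rnorm(kh * kw * c_out * c_in, sd = init_sd),
                  kh * kw * c_out, c_in),
       b = numeric(c_out))
}

conv_fwd <- function(layer, x, H, W, B) {
  cols <- .im2col_cpp(x, H, W, B, layer$kh, layer$kw, layer$stride, layer$pad)
  a <- act_fwd(add_bias(cols %*% layer$W, layer$b), layer$act)
  list(a = a, cols = cols,
       H = conv_out_dim(H, layer$kh, layer$stride, layer$pad),
       W = conv_out_dim(W, layer$kw, layer$stride, layer$pad))
}

conv_bwd <- function(layer, cache, da, H, W, B) {
  dz <- act_bwd(da, cache$a, layer$act)
  list(dW = crossprod(cache$cols, dz), db = colSums(dz),
       dx = .col2im_cpp(dz %*% t(layer$W), H, W, B,
                        layer$kh, layer$kw, layer$stride, layer$pad))
}

# transposed convolution: output H_out = stride*(H_in-1) + kh - 2*pad
deconv_fwd <- function(layer, x, H, W, B) {
  Ho <- layer$stride * (H - 1L) + layer$kh - 2L * layer$pad
  Wo <- layer$stride * (W - 1L) + layer$kw - 2L * layer$pad
  z <- .col2im_cpp(x %*% t(layer$W), Ho, Wo, B,
                   layer$kh, layer$kw, layer$stride, layer$pad)
  a <- act_fwd(add_bias(z, layer$b), layer$act)
  list(a = a, x = x, H = Ho, W = Wo)
}

deconv_bwd <- function(layer, cache, da, B) {
  dz <- act_bwd(da, cache$a, layer$act)
  dcols <- .im2col_cpp(dz, cache$H, cache$W, B,
                       layer$kh, layer$kw, layer$stride, layer$pad)
  list(dW = crossprod(dcols, cache$x), db = colSums(dz),
       dx = dcols %*% layer$W)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state[[i]]$m <- beta1 * state[[i]]$m + (1 - beta1) * g
    state[[i]]$v <- beta2 * state[[i]]$v + (1 - beta2) * g * g
    mhat <- state[[i]]$m / (1 - beta1^t)
    vhat <- state[[i]]$v / (1 - beta2^t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# get/set flat lists of weight matrices from a list of layers
layer_params <- function(layers) {
  out <- list()
  for (l in layers) out <- c(out, list(l$W), list(l$b))
  out
}

set_layer_params <- function(layers, params) {
  i <- 1L
  for (j in seq_along(layers)) {
    layers[[j]]$W <- params[[i]]
    layers[[j]]$b <- params[[i + 1L]]
    i <- i + 2L
  }
  layers
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic minibatch index blocks for one epoch
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
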