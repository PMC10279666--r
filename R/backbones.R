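# Backbone trunks. Two are shipped:
#   * "tiny_cnn"      - two 3x3 conv + leaky-ReLU + 2x2 max-pool stages,
#                       fully trainable; sized for desk-scale texture work.
#   * "mobilenet_v2"  - the full MobileNetV2 topology (stem conv, 17
#                       inverted-residual blocks, final 1x1 conv to 1280
#                       channels, ReLU6 activations), forward pass only and
#                       always frozen. Pretrained weights are not bundled;
#                       weights are He-initialised from the configured seed,
#                       so out of the box this trunk is an architecture
#                       reference and fixed random projection, not a
#                       transfer-learned extractor.

.TINY_FILTERS <- c(8L, 16L)

.build_tiny_trunk <- function(channels) {
  f <- .TINY_FILTERS
  mk_conv <- function(in_c, out_c) {
    fan_in <- 3L * 3L * in_c
    list(type = "conv", kh = 3L, kw = 3L, stride = 1L, pad = 1L,
         W = .he_weights(fan_in, out_c, fan_in), b = numeric(out_c))
  }
  list(mk_conv(channels, f[1]), list(type = "leaky"), list(type = "pool"),
       mk_conv(f[1], f[2]), list(type = "leaky"), list(type = "pool"))
}

.tiny_flatten_width <- function(image_size) {
  if (image_size %% 4L != 0L)
    stop("tiny_cnn requires image_size divisible by 4")
  (image_size %/% 4L)^2 * .TINY_FILTERS[2]
}

# Forward through the tiny trunk. Returns the flattened output (N x width)
# plus per-layer caches when `cache = TRUE` (needed for backprop and for
# class-activation maps). `last_conv` is the post-activation map of the
# final convolution, before the last pooling stage.
.tiny_forward <- function(trunk, x, slope, cache = FALSE) {
  caches <- vector("list", length(trunk))
  last_conv <- NULL
  for (li in seq_along(trunk)) {
    layer <- trunk[[li]]
    if (layer$type == "conv") {
      cf <- .conv_forward(x, layer)
      x <- cf$out
      if (cache) caches[[li]] <- cf$cache
    } else if (layer$type == "leaky") {
      lf <- .leaky_forward(x, slope)
      x <- lf$out
      if (cache) caches[[li]] <- lf$cache
      if (li == length(trunk) - 1L) last_conv <- x
    } else {
      pf <- .pool_forward(x)
      x <- pf$out
      if (cache) caches[[li]] <- pf$cache
    }
  }
  d <- dim(x)
  flat <- matrix(0, d[4], prod(d[1:3]))
  for (im in seq_len(d[4])) flat[im, ] <- as.vector(x[, , , im])
  list(flat = flat, out_dim = d, caches = caches, last_conv = last_conv)
}

# Backprop dflat (N x width) through the tiny trunk; returns weight grads
# per conv layer. `stop_at` (layer index) lets Grad-CAM recover the
# gradient at the last conv activation instead of running to the input.
.tiny_backward <- function(trunk, fwd, dflat, slope, stop_at = 0L) {
  d <- fwd$out_dim
  dx <- array(0, d)
  for (im in seq_len(d[4])) dx[, , , im] <- dflat[im, ]
  grads <- vector("list", length(trunk))
  for (li in rev(seq_along(trunk))) {
    if (li == stop_at) return(list(grads = grads, dx = dx))
    layer <- trunk[[li]]
    if (layer$type == "conv") {
      bb <- .conv_backward(dx, layer, fwd$caches[[li]])
      grads[[li]] <- list(dW = bb$dW, db = bb$db)
      dx <- bb$dx
    } else if (layer$type == "leaky") {
      dx <- .leaky_backward(dx, fwd$caches[[li]], slope)
    } else {
      dx <- .pool_backward(dx, fwd$caches[[li]])
    }
  }
  list(grads = grads, dx = dx)
}

# MobileNetV2 inverted-residual settings: expansion t, output channels c,
# repeats n, first-block stride s.
.MBV2_CFG <- list(
  c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
  c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1)
)

.build_mobilenet_trunk <- function(channels) {
  layers <- list()
  fan <- 3L * 3L * channels
  layers[[1]] <- list(type = "stem", kh = 3L, kw = 3L, stride = 2L, pad = 1L,
                      W = .he_weights(fan, 32L, fan), b = numeric(32L))
  in_c <- 32L
  for (blk in .MBV2_CFG) {
    t <- blk[1]; out_c <- as.integer(blk[2]); n <- blk[3]; s <- blk[4]
    for (rep_i in seq_len(n)) {
      stride <- if (rep_i == 1L) as.integer(s) else 1L
      exp_c <- as.integer(in_c * t)
      layers[[length(layers) + 1L]] <- list(
        type = "invres", stride = stride,
        use_res = (stride == 1L && in_c == out_c),
        expand = if (t != 1) .he_weights(in_c, exp_c, in_c) else NULL,
        dw = array(rnorm(9L * exp_c, sd = sqrt(2 / 9)), c(3L, 3L, exp_c)),
        project = .he_weights(exp_c, out_c, exp_c))
      in_c <- out_c
    }
  }
  layers[[length(layers) + 1L]] <- list(
    type = "headconv", W = .he_weights(in_c, 1280L, in_c), b = numeric(1280L))
  layers
}

.mbv2_flatten_width <- function(image_size) {
  s <- image_size
  for (i in 1:5) s <- (s - 1L) %/% 2L + 1L  # stem + four stride-2 stages
  s * s * 1280L
}

# Depthwise 3x3 convolution on one (H, W, C) image, pad 1.
.depthwise3x3 <- function(x, w, stride) {
  d <- dim(x)
  Hp <- d[1] + 2L; Wp <- d[2] + 2L
  xp <- array(0, c(Hp, Wp, d[3]))
  xp[1L + seq_len(d[1]), 1L + seq_len(d[2]), ] <- x
  oh <- (Hp - 3L) %/% stride + 1L
  ow <- (Wp - 3L) %/% stride + 1L
  out <- array(0, c(oh, ow, d[3]))
  for (di in 0:2) {
    ri <- seq.int(1L + di, by = stride, length.out = oh)
    for (dj in 0:2) {
      cj <- seq.int(1L + dj, by = stride, length.out = ow)
      out <- out + sweep(xp[ri, cj, , drop = FALSE], 3L,
                         w[di + 1L, dj + 1L, ], `*`)
    }
  }
  out
}

.pointwise <- function(x, W) {
  d <- dim(x)
  array(matrix(x, d[1] * d[2], d[3]) %*% W, c(d[1], d[2], ncol(W)))
}

# Forward one image (H, W, C) through the MobileNetV2 trunk; returns the
# final (h, w, 1280) activation (post ReLU6), whose flatten is the head
# input.
.mbv2_forward_one <- function(trunk, img) {
  x <- img
  for (layer in trunk) {
    if (layer$type == "stem") {
      xb <- array(x, c(dim(x), 1L))
      cf <- .conv_forward(xb, layer)
      x <- .relu6(cf$out[, , , 1, drop = TRUE])
      dim(x) <- dim(cf$out)[1:3]
    } else if (layer$type == "invres") {
      inp <- x
      if (!is.null(layer$expand)) x <- .relu6(.pointwise(x, layer$expand))
      x <- .relu6(.depthwise3x3(x, layer$dw, layer$stride))
      x <- .pointwise(x, layer$project)   # linear bottleneck, no activation
      if (layer$use_res) x <- x + inp
    } else {
      x <- .relu6(sweep(.pointwise(x, layer$W), 3L, layer$b, `+`))
    }
  }
  x
}

.mbv2_forward <- function(trunk, x) {
  d <- dim(x)
  first <- .mbv2_forward_one(trunk, array(x[, , , 1], d[1:3]))
  width <- length(first)
  flat <- matrix(0, d[4], width)
  flat[1, ] <- as.vector(first)
  if (d[4] > 1L) for (im in 2:d[4])
    flat[im, ] <- as.vector(.mbv2_forward_one(trunk, array(x[, , , im], d[1:3])))
  list(flat = flat, out_dim = c(dim(first), d[4]), last_conv = first)
}
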