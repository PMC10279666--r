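#' Gradient-weighted class-activation map
#'
#' Computes the gradient of the target class score (pre-softmax logit)
#' with respect to the last convolutional activations of the checkpoint,
#' averages it spatially into per-channel weights, forms the weighted sum
#' of the activation maps, rectifies (negative evidence is discarded),
#' upsamples the surviving map bilinearly to the input size and min-max
#' normalises it to `[0, 1]`, so the hottest pixel reads exactly 1. For the `"tiny_cnn"` backbone the tapped layer is the
#' post-activation output of the second convolution; for `"mobilenet_v2"`
#' it is the final 1x1 convolution output preceding the flatten.
#'
#' If rectification kills every activation the map is returned as all
#' zeros with a warning rather than an error.
#'
#' @param checkpoint a [CNNModel-class].
#' @param image `(H, W, C)` array (or `H x W` matrix for single-channel
#'   models) matching the checkpoint's input geometry.
#' @param class_index 1-based class whose evidence is localised.
#' @return an [ActivationMap-class].
#' @export
gradCAM <- function(checkpoint, image, class_index) {
  cfg <- checkpoint@config
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!identical(dim(image)[1:3],
                 c(cfg@image_size, cfg@image_size, cfg@channels)))
    stop(sprintf("image must be %d x %d x %d for this checkpoint",
                 cfg@image_size, cfg@image_size, cfg@channels))
  class_index <- as.integer(class_index)
  if (class_index < 1L || class_index > cfg@num_classes)
    stop("class_index out of range")
  slope <- cfg@leaky_slope
  image <- .normalize_input(image)
  if (cfg@backbone_id == "tiny_cnn") {
    x4 <- array(image, c(dim(image), 1L))
    tf <- .tiny_forward(checkpoint@trunk, x4, slope, cache = TRUE)
    A <- tf$last_conv[, , , 1, drop = TRUE]
    dim(A) <- dim(tf$last_conv)[1:3]
    hf <- .head_forward(checkpoint@head, tf$flat, slope, cache = TRUE)
    dz <- matrix(0, 1L, cfg@num_classes); dz[1L, class_index] <- 1
    hb <- .head_backward(checkpoint@head, hf$cache, dz, slope)
    # gradient back through the final pooling stage only
    tb <- .tiny_backward(checkpoint@trunk, tf, hb$dflat, slope,
                         stop_at = length(checkpoint@trunk) - 1L)
    dA <- tb$dx[, , , 1, drop = TRUE]
    dim(dA) <- dim(A)
  } else {
    A <- .mbv2_forward_one(checkpoint@trunk, image)
    flat <- matrix(as.vector(A), 1L)
    hf <- .head_forward(checkpoint@head, flat, slope, cache = TRUE)
    dz <- matrix(0, 1L, cfg@num_classes); dz[1L, class_index] <- 1
    hb <- .head_backward(checkpoint@head, hf$cache, dz, slope)
    dA <- array(hb$dflat[1L, ], dim(A))
  }
  wts <- apply(dA, 3L, mean)                       # channel importance
  cam <- apply(sweep(A, 3L, wts, `*`), c(1L, 2L), sum)
  cam[cam < 0] <- 0
  mx <- max(cam)
  if (mx <= 0) {
    warning("no positive class evidence survived rectification; returning a zero map")
    heat <- matrix(0, dim(image)[1], dim(image)[2])
  } else {
    # upsample first, then min-max normalise, so the rendered map attains
    # exactly 1 at its hottest pixel
    heat <- .bilinear_resize(cam, dim(image)[1], dim(image)[2])
    heat <- pmax(heat, 0)
    mn <- min(heat); mx <- max(heat)
    heat <- if (mn < mx) (heat - mn) / (mx - mn) else heat / mx
  }
  new("ActivationMap", heat = heat, class_index = class_index,
      snapshot_index = checkpoint@snapshot_index)
}

.bilinear_resize <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  out <- EBImage::resize(EBImage::Image(m), w = h, h = w, filter = "bilinear")
  matrix(EBImage::imageData(out), h, w)
}

#' Blend an activation map onto its image
#'
#' Colour-maps the heat values (dark blue through cyan and yellow to red)
#' and alpha-blends the result over the image: `alpha = 0` returns the
#' original image, `alpha = 1` the pure heat-map rendering.
#'
#' @param image `(H, W, C)` array (1 or 3 channels) or `H x W` matrix with
#'   values in `[0, 1]`.
#' @param map an [ActivationMap-class] of matching spatial size.
#' @param alpha blend weight of the heat map, in `[0, 1]`.
#' @return an `(H, W, 3)` array in `[0, 1]`.
#' @export
overlayHeatmap <- function(image, map, alpha = 0.5) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  h <- map@heat
  if (!all(dim(image)[1:2] == dim(h)))
    stop("image and activation map spatial shapes differ")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  rgb_img <- if (dim(image)[3] == 3L) image else
    array(rep(image[, , 1L], 3L), c(dim(h), 3L))
  ramp <- grDevices::colorRamp(c("#000080", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF0000"))
  heat_rgb <- array(ramp(as.vector(h)) / 255, c(dim(h), 3L))
  out <- (1 - alpha) * rgb_img + alpha * heat_rgb
  pmin(pmax(out, 0), 1)
}

#' Write an overlay (or any image array) as PNG
#'
#' @param img `H x W` matrix or `(H, W, C)` array in `[0, 1]`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeImagePNG <- function(img, file) {
  png::writePNG(img, file)
  invisible(file)
}

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap: %d x %d heat map for class %d (snapshot %d), max %.3f\n",
              nrow(object@heat), ncol(object@heat), object@class_index,
              object@snapshot_index, max(object@heat)))
})
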