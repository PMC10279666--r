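#' Specify a procedural texture image set
#'
#' @param num_classes number of texture classes.
#' @param per_class images per class (balanced).
#' @param image_size image side in pixels.
#' @param channels output channels; the grayscale texture is replicated.
#' @param frequencies grating spatial frequency per class, in cycles per
#'   image side (integers keep the spectral peak on an FFT bin).
#' @param orientations grating orientation per class, degrees.
#' @param blob_density expected Poisson blob count per class.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param region where the class-discriminative grating lives: `"full"` or
#'   a quadrant `"q1"` (top-left), `"q2"` (bottom-left), `"q3"`
#'   (top-right), `"q4"` (bottom-right); recorded so localisation tests
#'   know the ground truth.
#' @param seed RNG seed.
#' @return a [TextureSpec-class].
#' @export
textureSpec <- function(num_classes = 3L, per_class = 40L, image_size = 32L,
                        channels = 1L,
                        frequencies = seq(3, by = 3, length.out = num_classes),
                        orientations = seq(0, by = 45, length.out = num_classes),
                        blob_density = seq(0, by = 4, length.out = num_classes),
                        noise_sd = 0.05, region = "full", seed = 1L) {
  new("TextureSpec", num_classes = as.integer(num_classes),
      per_class = as.integer(per_class), image_size = as.integer(image_size),
      channels = as.integer(channels), frequencies = as.numeric(frequencies),
      orientations = as.numeric(orientations),
      blob_density = as.numeric(blob_density),
      noise_sd = as.numeric(noise_sd), region = region,
      seed = as.integer(seed))
}

.region_mask <- function(size, region) {
  m <- matrix(region == "full", size, size)
  half <- size %/% 2L
  rows <- if (region %in% c("q1", "q3")) seq_len(half) else half + seq_len(size - half)
  cols <- if (region %in% c("q1", "q2")) seq_len(half) else half + seq_len(size - half)
  if (region != "full") m[rows, cols] <- TRUE
  m
}

#' Generate a labelled multi-class texture image set
#'
#' Each image is a mid-gray canvas carrying its class's sinusoidal grating
#' (random phase per image) inside the spec's region, a Poisson field of
#' small Gaussian blobs at the class density, and i.i.d. Gaussian pixel
#' noise; pixel values are clipped to `[0, 1]`. A stratified 60/20/20
#' train/val/test split manifest is drawn from the same seed, so identical
#' specs give pixel-identical datasets and identical splits.
#'
#' @param spec a [TextureSpec-class].
#' @return list with `images` (`(H, W, C, N)` array), `labels` (1-based
#'   integers), `splits` (list of index vectors `train`/`val`/`test`),
#'   `region_mask` (logical `H x W`, where the discriminative grating
#'   lives) and `spec`.
#' @export
makeTextureDataset <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  S <- spec@image_size
  n <- spec@num_classes * spec@per_class
  labels <- rep(seq_len(spec@num_classes), each = spec@per_class)
  imgs <- array(0, c(S, S, spec@channels, n))
  mask <- .region_mask(S, spec@region)
  xc <- matrix(rep(seq_len(S) - 1L, each = S), S, S)   # column coordinate
  yc <- matrix(rep(seq_len(S) - 1L, times = S), S, S)  # row coordinate
  for (i in seq_len(n)) {
    cl <- labels[i]
    th <- spec@orientations[cl] * pi / 180
    phase <- runif(1, 0, 2 * pi)
    grating <- 0.25 * sin(2 * pi * spec@frequencies[cl] *
                            (xc * cos(th) + yc * sin(th)) / S + phase)
    img <- matrix(0.5, S, S)
    img[mask] <- img[mask] + grating[mask]
    nb <- rpois(1, spec@blob_density[cl])
    if (nb > 0) for (b in seq_len(nb)) {
      cx <- runif(1, 1, S); cy <- runif(1, 1, S)
      img <- img + 0.2 * exp(-((xc + 1 - cx)^2 + (yc + 1 - cy)^2) / (2 * 1.5^2))
    }
    if (spec@noise_sd > 0)
      img <- img + matrix(rnorm(S * S, sd = spec@noise_sd), S, S)
    img <- pmin(pmax(img, 0), 1)
    for (ch in seq_len(spec@channels)) imgs[, , ch, i] <- img
  }
  splits <- .stratified_split(labels, c(train = 0.6, val = 0.2, test = 0.2))
  list(images = imgs, labels = labels, splits = splits, region_mask = mask,
       spec = spec)
}

# Seeded stratified split into named fractions (uses the current RNG
# stream). Remainders go to the earlier-named parts.
.stratified_split <- function(labels, frac) {
  parts <- setNames(vector("list", length(frac)), names(frac))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    sizes <- floor(frac * length(idx))
    left <- length(idx) - sum(sizes)
    if (left > 0) sizes[seq_len(left)] <- sizes[seq_len(left)] + 1L
    off <- 0L
    for (p in names(frac)) {
      parts[[p]] <- c(parts[[p]], idx[off + seq_len(sizes[p])])
      off <- off + sizes[p]
    }
  }
  lapply(parts, sort)
}

#' Specify a planted-structure feature matrix
#'
#' @param num_classes,samples_per_class balanced class layout.
#' @param n_informative columns whose class means are separated.
#' @param n_redundant noisy copies of informative columns (cycled),
#'   emulating the cross-snapshot redundancy that feature selection should
#'   prune.
#' @param n_noise class-independent standard-Gaussian columns.
#' @param class_separation Euclidean distance between the two closest
#'   class means in the informative subspace.
#' @param noise_sd within-class and copy-noise standard deviation.
#' @param split_frac named train/val/test fractions (must sum to 1).
#' @param seed RNG seed.
#' @return a [PlantedFeatureSpec-class].
#' @export
plantedFeatureSpec <- function(num_classes = 4L, samples_per_class = 60L,
                               n_informative = 4L, n_redundant = 8L,
                               n_noise = 52L, class_separation = 4,
                               noise_sd = 1,
                               split_frac = c(train = 0.6, val = 0.2,
                                              test = 0.2),
                               seed = 1L) {
  new("PlantedFeatureSpec", num_classes = as.integer(num_classes),
      samples_per_class = as.integer(samples_per_class),
      n_informative = as.integer(n_informative),
      n_redundant = as.integer(n_redundant), n_noise = as.integer(n_noise),
      class_separation = as.numeric(class_separation),
      noise_sd = as.numeric(noise_sd), split_frac = split_frac,
      seed = as.integer(seed))
}

#' Generate a feature matrix with planted informative structure
#'
#' Columns come in three blocks: informative (class-dependent Gaussian
#' means whose closest pair sits `class_separation` apart), redundant
#' (informative columns plus Gaussian copy noise) and noise
#' (class-independent standard Gaussians). The homoscedastic within-class
#' noise has `noise_sd` standard deviation. Rows are balanced across
#' classes and split into disjoint stratified train/val/test parts; the
#' ground-truth informative mask and the per-column block type are
#' recorded.
#'
#' @param spec a [PlantedFeatureSpec-class].
#' @return list with `train`/`val`/`test` ([FeatureMatrix-class] objects),
#'   `values`/`labels` (the full unsplit data), `truth_mask` (0/1,
#'   informative columns), `column_type` (factor of
#'   informative/redundant/noise) and `spec`.
#' @export
makePlantedFeatures <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  K <- spec@num_classes
  n <- K * spec@samples_per_class
  labels <- rep(seq_len(K), each = spec@samples_per_class)
  p_inf <- spec@n_informative
  # class means in the informative subspace, rescaled so the closest pair
  # is exactly class_separation apart
  mu <- matrix(rnorm(K * p_inf), K, p_inf)
  mu <- sweep(mu, 2L, colMeans(mu))
  dmin <- min(dist(mu))
  if (dmin == 0) stop("degenerate class means; change the seed")
  mu <- mu * spec@class_separation / dmin
  inf <- mu[labels, , drop = FALSE] +
    matrix(rnorm(n * p_inf, sd = spec@noise_sd), n, p_inf)
  red <- NULL
  if (spec@n_redundant > 0L) {
    src <- rep_len(seq_len(p_inf), spec@n_redundant)
    red <- inf[, src, drop = FALSE] +
      matrix(rnorm(n * spec@n_redundant, sd = spec@noise_sd), n,
             spec@n_redundant)
  }
  noise <- if (spec@n_noise > 0L)
    matrix(rnorm(n * spec@n_noise), n, spec@n_noise) else NULL
  values <- cbind(inf, red, noise)
  column_type <- factor(rep(c("informative", "redundant", "noise"),
                            c(p_inf, spec@n_redundant, spec@n_noise)),
                        levels = c("informative", "redundant", "noise"))
  truth_mask <- as.integer(column_type == "informative")
  splits <- .stratified_split(labels, spec@split_frac)
  fm_of <- function(part, tag) FeatureMatrix(
    values[splits[[part]], , drop = FALSE], labels[splits[[part]]], tag)
  list(train = fm_of("train", "train"), val = fm_of("val", "val"),
       test = fm_of("test", "test"), values = values, labels = labels,
       truth_mask = truth_mask, column_type = column_type, spec = spec)
}
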