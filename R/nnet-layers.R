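# Internal CNN layer primitives. Images are arrays (H, W, C, N), column
# major; convolutions run through im2col so the inner product is a single
# BLAS matrix multiplication. Everything here is deterministic given the
# R RNG stream.

.pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# Linear gather indices into one padded (Hp, Wp, C) image: rows are output
# pixels (column-major over oh, ow), columns are patch entries (kh, kw, C).
.im2col_index <- function(H, W, C, kh, kw, stride, pad) {
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  oh <- (Hp - kh) %/% stride + 1L
  ow <- (Wp - kw) %/% stride + 1L
  oi <- (seq_len(oh) - 1L) * stride   # top-left row offset of each patch
  oj <- (seq_len(ow) - 1L) * stride
  base_i <- rep(oi, times = ow)       # output pixels, i fastest
  base_j <- rep(oj, each = oh)
  di <- rep(seq_len(kh), times = kw * C)
  dj <- rep(rep(seq_len(kw), each = kh), times = C)
  dc <- rep(seq_len(C), each = kh * kw)
  # idx[p, k] = linear index of patch entry k for output pixel p
  idx <- outer(base_i, di, `+`) + Hp * (outer(base_j, dj, `+`) - 1L)
  idx <- sweep(idx, 2L, Hp * Wp * (dc - 1L), `+`)
  list(idx = idx, oh = oh, ow = ow, Hp = Hp, Wp = Wp)
}

# x: (H, W, C, N) -> cols: (N*oh*ow, kh*kw*C), image-major row blocks.
.im2col <- function(x, kh, kw, stride, pad, info = NULL) {
  d <- dim(x)
  if (is.null(info))
    info <- .im2col_index(d[1], d[2], d[3], kh, kw, stride, pad)
  xp <- .pad_hw(x, pad)
  n <- d[4]
  P <- info$oh * info$ow
  len <- info$Hp * info$Wp * d[3]
  cols <- matrix(0, n * P, ncol(info$idx))
  xf <- as.vector(xp)
  for (im in seq_len(n))
    cols[(im - 1L) * P + seq_len(P), ] <- xf[info$idx + (im - 1L) * len]
  list(cols = cols, info = info, in_dim = d)
}

# Scatter-add of dcols back to the (H, W, C, N) input gradient.
.col2im <- function(dcols, info, in_dim, pad) {
  n <- in_dim[4]
  P <- info$oh * info$ow
  len <- info$Hp * info$Wp * in_dim[3]
  dxf <- numeric(n * len)
  for (im in seq_len(n)) {
    off <- (im - 1L) * len
    rows <- (im - 1L) * P + seq_len(P)
    for (k in seq_len(ncol(info$idx)))
      dxf[info$idx[, k] + off] <- dxf[info$idx[, k] + off] + dcols[rows, k]
  }
  dxp <- array(dxf, c(info$Hp, info$Wp, in_dim[3], n))
  if (pad > 0L)
    dxp <- dxp[pad + seq_len(in_dim[1]), pad + seq_len(in_dim[2]), , ,
               drop = FALSE]
  dxp
}

.conv_forward <- function(x, layer, info = NULL) {
  ic <- .im2col(x, layer$kh, layer$kw, layer$stride, layer$pad, info)
  out_mat <- ic$cols %*% layer$W          # (N*P) x F
  out_mat <- sweep(out_mat, 2L, layer$b, `+`)
  n <- ic$in_dim[4]; P <- ic$info$oh * ic$info$ow; f <- ncol(layer$W)
  out <- array(0, c(ic$info$oh, ic$info$ow, f, n))
  for (im in seq_len(n))
    out[, , , im] <- out_mat[(im - 1L) * P + seq_len(P), ]
  list(out = out, cache = ic)
}

.conv_backward <- function(dout, layer, cache) {
  n <- cache$in_dim[4]; P <- cache$info$oh * cache$info$ow
  f <- ncol(layer$W)
  dout_mat <- matrix(0, n * P, f)
  for (im in seq_len(n))
    dout_mat[(im - 1L) * P + seq_len(P), ] <- matrix(dout[, , , im], P, f)
  dW <- crossprod(cache$cols, dout_mat)
  db <- colSums(dout_mat)
  dx <- .col2im(dout_mat %*% t(layer$W), cache$info, cache$in_dim, layer$pad)
  list(dW = dW, db = db, dx = dx)
}

# 2x2 max pooling, stride 2; ties resolved first-wins in (top-left,
# bottom-left, top-right, bottom-right) order for determinism.
.pool_forward <- function(x) {
  d <- dim(x)
  xr <- array(x, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  s1 <- xr[1, , 1, , , , drop = FALSE]; dim(s1) <- dim(xr)[-c(1, 3)]
  s2 <- xr[2, , 1, , , , drop = FALSE]; dim(s2) <- dim(s1)
  s3 <- xr[1, , 2, , , , drop = FALSE]; dim(s3) <- dim(s1)
  s4 <- xr[2, , 2, , , , drop = FALSE]; dim(s4) <- dim(s1)
  out <- pmax(s1, s2, s3, s4)
  list(out = out, cache = list(slices = list(s1, s2, s3, s4), out = out,
                               in_dim = d))
}

.pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  sl <- cache$slices
  taken <- array(FALSE, dim(cache$out))
  dxr <- array(0, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  pos <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    m <- (sl[[k]] == cache$out) & !taken
    taken <- taken | m
    dxr[pos[[k]][1], , pos[[k]][2], , , ] <- dout * m
  }
  array(dxr, d)
}

.leaky_forward <- function(x, slope) {
  neg <- which(x < 0)   # which() drops NA, so divergence surfaces at the
  x[neg] <- x[neg] * slope   # loss check instead of crashing here
  list(out = x, cache = neg)
}

.leaky_backward <- function(dout, neg, slope) {
  dout[neg] <- dout[neg] * slope
  dout
}

.relu6 <- function(x) pmin(pmax(x, 0), 6)

.dense_forward <- function(X, W, b) sweep(X %*% W, 2L, b, `+`)

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy of 1-based integer labels; dz is the gradient of the
# mean loss w.r.t. the logits.
.softmax_xent <- function(logits, y) {
  p <- .softmax(logits)
  n <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], eps)))
  dz <- p
  dz[cbind(seq_len(n), y)] <- dz[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dz = dz / n)
}

.he_weights <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# SGD with momentum, PyTorch convention: v <- mu v + g; w <- w - lr v.
.sgd_step <- function(param, grad, vel, lr, mu) {
  vel <- mu * vel + grad
  list(param = param - lr * vel, vel = vel)
}
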