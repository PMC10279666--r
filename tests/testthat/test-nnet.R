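# The layer engine is hand-rolled, so its gradients are verified against
# central finite differences of the loss on a tiny model.

loss_of <- function(model, x, y) {
  fw <- snapshotFS:::.model_forward(model, x)
  snapshotFS:::.softmax_xent(fw$head$logits, y)$loss
}

test_that("analytic gradients match finite differences through head and trunk", {
  model <- buildModel(tiny_config())
  b <- tiny_batch(n = 4L)
  fw <- snapshotFS:::.model_forward(model, b$x, cache = TRUE)
  sc <- snapshotFS:::.softmax_xent(fw$head$logits, b$y)
  hb <- snapshotFS:::.head_backward(model@head, fw$head$cache, sc$dz, 0.01)
  tb <- snapshotFS:::.tiny_backward(model@trunk, fw$trunk, hb$dflat, 0.01)

  eps <- 1e-6
  check_entries <- function(get, set, grad, idx) {
    for (i in idx) {
      m1 <- set(model, i, eps); m2 <- set(model, i, -eps)
      num <- (loss_of(m1, b$x, b$y) - loss_of(m2, b$x, b$y)) / (2 * eps)
      expect_equal(num, grad[i], tolerance = 1e-4)
    }
  }
  set.seed(1)
  # head weights
  check_entries(NULL, function(m, i, e) { m@head$W2[i] <- m@head$W2[i] + e; m },
                hb$dW2, sample(length(model@head$W2), 4))
  check_entries(NULL, function(m, i, e) { m@head$b3[i] <- m@head$b3[i] + e; m },
                hb$db3, seq_along(model@head$b3))
  # first conv layer weights (gradient flowed through both pools)
  check_entries(NULL, function(m, i, e) {
    m@trunk[[1]]$W[i] <- m@trunk[[1]]$W[i] + e; m },
    tb$grads[[1]]$dW, sample(length(model@trunk[[1]]$W), 4))
  check_entries(NULL, function(m, i, e) {
    m@trunk[[4]]$W[i] <- m@trunk[[4]]$W[i] + e; m },
    tb$grads[[4]]$dW, sample(length(model@trunk[[4]]$W), 4))
})

test_that("softmax head yields a probability distribution", {
  model <- buildModel(tiny_config(num_classes = 3L))
  b <- tiny_batch(n = 5L, num_classes = 3L)
  p <- predictProba(model, b$x)
  expect_identical(dim(p), c(5L, 3L))
  expect_true(all(p > 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  # single (H, W, C) image accepted as batch of one
  p1 <- predictProba(model, b$x[, , , 1])
  expect_equal(p1[1, ], p[1, ], tolerance = 1e-12)
})

test_that("max pooling keeps the maximum and routes gradient to it", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  pf <- snapshotFS:::.pool_forward(x)
  expect_equal(as.vector(pf$out), c(6, 8, 14, 16))
  d <- array(1, c(2, 2, 1, 1))
  dx <- snapshotFS:::.pool_backward(d, pf$cache)
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1, 1], 1)  # position of the value 6
  expect_equal(dx[1, 1, 1, 1], 0)
})
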