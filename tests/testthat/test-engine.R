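# A small graph exercising every trainable kind plus residual merge and
# both pooling flavours; cheap enough for finite-difference checks.
mixed_graph <- function() {
  model_graph(list(
    layer_node("in", "input", params = list(shape = c(8, 8, 2))),
    layer_node("c1", "conv2d",
               params = list(filters = 3, kernel = 3, stride = 1,
                             padding = "same"),
               preds = "in"),
    layer_node("bn1", "batch_norm", preds = "c1"),
    layer_node("r1", "relu_activation", preds = "bn1"),
    layer_node("s1", "separable_conv2d",
               params = list(filters = 3, kernel = 3, padding = "same"),
               preds = "r1"),
    layer_node("bn2", "batch_norm", preds = "s1"),
    layer_node("add", "add_merge", preds = c("bn2", "r1")),
    layer_node("mp", "max_pool",
               params = list(window = 2, stride = 2), preds = "add"),
    layer_node("tk", "avg_topk_pool",
               params = list(window = 2, stride = 2, K = 2), preds = "mp"),
    layer_node("gap", "global_avg_pool", preds = "tk"),
    layer_node("fc", "dense", params = list(units = 3), preds = "gap"),
    layer_node("soft", "softmax", preds = "fc")
  ), "soft")
}

test_that("model_forward produces valid probabilities and caches", {
  m <- init_model(mixed_graph(), seed = 8)
  x <- array(rnorm(8 * 8 * 2 * 4), dim = c(8, 8, 2, 4))
  fw <- model_forward(m, x, training = TRUE, keep_all = TRUE)
  expect_equal(dim(fw$out), c(4L, 3L))
  expect_equal(rowSums(fw$out), rep(1, 4), tolerance = 1e-12)
  expect_true(all(fw$out > 0))
  expect_equal(dim(fw$cache$mp$out), c(4L, 4L, 3L, 4L))
  # single image is promoted to a batch of one
  one <- model_forward(m, x[, , , 1])$out
  expect_equal(dim(one), c(1L, 3L))
  expect_error(model_forward(m, x[1:4, , , , drop = FALSE]),
               "does not match")
})

test_that("init_model is seed-deterministic and restores the RNG state", {
  g <- mixed_graph()
  set.seed(99); before <- runif(1)
  set.seed(99)
  m1 <- init_model(g, seed = 4)
  after <- runif(1)
  expect_identical(before, after)  # global RNG stream untouched
  m2 <- init_model(g, seed = 4)
  expect_identical(m1$weights, m2$weights)
  m3 <- init_model(g, seed = 5)
  expect_false(identical(m1$weights$c1$W, m3$weights$c1$W))
  # batch norm starts as the identity transform
  expect_equal(m1$weights$bn1$gamma, rep(1, 3))
  expect_equal(m1$weights$bn1$mean, rep(0, 3))
})

test_that("model gradients match central finite differences", {
  m <- init_model(mixed_graph(), seed = 13)
  x <- array(rnorm(8 * 8 * 2 * 3), dim = c(8, 8, 2, 3))
  labels <- c(1L, 3L, 2L)
  fw <- model_forward(m, x, training = TRUE, keep_all = TRUE)
  bw <- dermcnn:::model_backward(m, fw$cache, labels)
  loss_at <- function(model) {
    f <- model_forward(model, x, training = TRUE, keep_all = TRUE)
    dermcnn:::model_backward(model, f$cache, labels)$loss
  }
  set.seed(14)
  worst <- 0
  for (id in names(bw$grads)) {
    for (nm in names(bw$grads[[id]])) {
      w <- m$weights[[id]][[nm]]
      picks <- sample(length(w), min(4L, length(w)))
      for (i in picks) {
        h <- 1e-5
        mp <- m; mp$weights[[id]][[nm]][i] <- w[i] + h
        mm <- m; mm$weights[[id]][[nm]][i] <- w[i] - h
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
        an <- bw$grads[[id]][[nm]][i]
        worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd), abs(an)))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("batch norm switches between batch and running statistics", {
  m <- init_model(mixed_graph(), seed = 21)
  x <- array(rnorm(8 * 8 * 2 * 4, mean = 3), dim = c(8, 8, 2, 4))
  tr <- model_forward(m, x, training = TRUE, keep_all = TRUE)
  # training mode standardises with batch moments: mean ~0, sd ~1 per channel
  bn <- tr$cache$bn1$out
  ch_means <- apply(bn, 3, mean)
  expect_equal(unname(ch_means), rep(0, 3), tolerance = 1e-6)
  # inference mode uses the (identity) running moments instead
  inf <- model_forward(m, x, training = FALSE, keep_all = TRUE)
  expect_gt(max(abs(apply(inf$cache$bn1$out, 3, mean))), 0.5)
})

test_that("adam_step applies bias-corrected updates and BN refresh", {
  m <- init_model(mixed_graph(), seed = 31)
  x <- array(rnorm(8 * 8 * 2 * 4), dim = c(8, 8, 2, 4))
  fw <- model_forward(m, x, training = TRUE, keep_all = TRUE)
  bw <- dermcnn:::model_backward(m, fw$cache, c(1L, 2L, 3L, 1L))
  st <- dermcnn:::adam_init(m$weights)
  upd <- dermcnn:::adam_step(m, bw$grads, bw$bn_updates, st, lr = 1e-3, t = 1)
  g <- bw$grads$fc$W
  # first step of Adam moves each coordinate by ~lr * sign(gradient)
  delta <- upd$model$weights$fc$W - m$weights$fc$W
  expect_equal(delta[g != 0], -1e-3 * sign(g[g != 0]), tolerance = 1e-2)
  # running moments moved toward the batch moments
  expect_false(identical(upd$model$weights$bn1$mean, m$weights$bn1$mean))
  expect_equal(upd$model$weights$bn1$mean,
               0.99 * m$weights$bn1$mean + 0.01 * bw$bn_updates$bn1$mean)
})
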