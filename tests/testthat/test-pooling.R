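# Brute-force R oracle for Avg-TopK pooling, valid padding, square window.
oracle_avg_topk <- function(x, window, stride, K) {
  d <- dim(x)
  oh <- (d[1] - window) %/% stride + 1L
  ow <- (d[2] - window) %/% stride + 1L
  y <- array(0, dim = c(oh, ow, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (j in seq_len(ow)) for (i in seq_len(oh)) {
      h0 <- (i - 1L) * stride; w0 <- (j - 1L) * stride
      win <- x[h0 + seq_len(window), w0 + seq_len(window), c, n]
      y[i, j, c, n] <- topk_mean(as.vector(win), K)
    }
  y
}

test_that("topk_mean is permutation invariant and non-increasing in K", {
  set.seed(1)
  for (rep in 1:20) {
    v <- rnorm(9)
    expect_equal(topk_mean(v, 3), topk_mean(sample(v), 3))
    means <- vapply(1:9, function(k) topk_mean(v, k), numeric(1))
    expect_true(all(diff(means) <= 1e-12))
    expect_equal(means[1], max(v))
    expect_equal(means[9], mean(v))
  }
  expect_error(topk_mean(numeric(0), 3), "empty")
  expect_error(topk_mean(1:3, 0), "K must be")
  # K beyond the window size clamps to the full window
  expect_equal(topk_mean(1:4, 99), mean(1:4))
})

test_that("avg_topk_pool2d matches the brute-force window oracle", {
  set.seed(7)
  x <- array(rnorm(6 * 7 * 2 * 3), dim = c(6, 7, 2, 3))
  for (cfg in list(c(2, 2, 1), c(2, 2, 4), c(3, 1, 3), c(3, 2, 5))) {
    spec <- pooling_spec(window = cfg[1], stride = cfg[2], K = cfg[3])
    got <- avg_topk_pool2d(x, spec)
    attr(got, "cache") <- NULL
    expect_equal(got, oracle_avg_topk(x, cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-12)
  }
})

test_that("same padding excludes padded cells and clamps K", {
  # 3x3 single-channel map, 2x2 window, stride 2, same padding:
  # the bottom/right windows only contain one real value.
  x <- array(matrix(c(1, 4, 7,
                      2, 5, 8,
                      3, 6, 9), 3, 3), dim = c(3, 3, 1, 1))
  spec <- pooling_spec(window = 2, stride = 2, K = 4, padding = "same")
  y <- avg_topk_pool2d(x, spec)
  expect_equal(dim(y), c(2L, 2L, 1L, 1L))
  expect_equal(y[1, 1, 1, 1], mean(c(1, 2, 4, 5)))  # full window, K clamps 4
  expect_equal(y[2, 1, 1, 1], mean(c(7, 8)))        # bottom edge: 2 real cells
  expect_equal(y[1, 2, 1, 1], mean(c(3, 6)))        # right edge: 2 real cells
  expect_equal(y[2, 2, 1, 1], 9)                    # corner: 1 real cell
})

test_that("avg_topk_backward matches finite differences away from ties", {
  set.seed(11)
  x <- array(rnorm(5 * 5 * 2 * 2), dim = c(5, 5, 2, 2))
  spec <- pooling_spec(window = 2, stride = 1, K = 2)
  y <- avg_topk_pool2d(x, spec)
  cache <- attr(y, "cache")
  up <- array(rnorm(length(y)), dim = dim(y))
  dx <- avg_topk_backward(up, cache)
  f <- function(v) {
    xi <- array(v, dim = dim(x))
    sum(array(avg_topk_pool2d(xi, spec), dim = dim(y)) * up)
  }
  g <- numeric_gradient(f, as.vector(x))
  expect_lt(max(abs(as.vector(dx) - g)) / max(abs(g)), 1e-6)
})

test_that("avg_topk_backward rejects mismatched caches", {
  x <- array(rnorm(16), dim = c(4, 4, 1, 1))
  y <- avg_topk_pool2d(x, pooling_spec(2, 2, K = 2))
  cache <- attr(y, "cache")
  expect_error(avg_topk_backward(array(0, c(3, 3, 1, 1)), cache),
               "does not match")
  expect_error(avg_topk_backward(y, list()), "cache")
})

test_that("replace_max_pooling swaps every max_pool and nothing else", {
  g <- micro_graph()
  kinds0 <- vapply(g$nodes, function(n) n$kind, character(1))
  g2 <- replace_max_pooling(g, K = 3)
  kinds <- vapply(g2$nodes, function(n) n$kind, character(1))
  expect_false(any(kinds == "max_pool"))
  expect_equal(sum(kinds == "avg_topk_pool"), sum(kinds0 == "max_pool"))
  expect_identical(names(g2$nodes), names(g$nodes))
  for (id in names(g$nodes)[kinds0 == "max_pool"]) {
    expect_identical(g2$nodes[[id]]$params$K, 3L)
    expect_identical(g2$nodes[[id]]$params$window, g$nodes[[id]]$params$window)
    expect_identical(g2$nodes[[id]]$preds, g$nodes[[id]]$preds)
  }
  # shapes are preserved, so the swapped graph is drop-in trainable
  expect_identical(infer_shapes(g2), infer_shapes(g))
  g3 <- model_graph(list(
    layer_node("in", "input", params = list(shape = c(4, 4, 1))),
    layer_node("gap", "global_avg_pool", preds = "in"),
    layer_node("fc", "dense", params = list(units = 2), preds = "gap"),
    layer_node("soft", "softmax", preds = "fc")
  ), "soft")
  expect_message(replace_max_pooling(g3), "no max_pool")
})
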