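test_that("activation_sparsity averages per-sample zero fractions", {
  a1 <- c(0, 1, 0, 2)        # 2/4 zero
  a2 <- c(0, 0, 0, 5)        # 3/4 zero
  expect_equal(activation_sparsity(list(a1, a2)), (0.5 + 0.75) / 2)
  # array form: last dimension indexes samples
  arr <- array(c(a1, a2), dim = c(2, 2, 1, 2))
  expect_equal(activation_sparsity(arr), (0.5 + 0.75) / 2)
  # tolerance widens the zero set
  expect_equal(activation_sparsity(list(c(0.01, 1)), tolerance = 0.05), 0.5)
  expect_error(activation_sparsity(list()), "empty")
})

test_that("select_cut picks the maximal sparsity, earliest on ties", {
  prof <- data.frame(layer_id = c("a", "b", "c"),
                     sparsity = c(0.2, 0.9, 0.9))
  expect_identical(select_cut(prof), "b")
  expect_error(select_cut(prof[0, ]), "empty")
  expect_error(select_cut(data.frame(layer_id = "a", sparsity = 1.2)),
               "\\[0, 1\\]")
})

test_that("profile_model records candidates in topological order", {
  g <- tiny_graph(input_size = 8L, channels = 1L, n_classes = 3L)
  m <- init_model(g, seed = 3)
  batch <- array(rnorm(8 * 8 * 1 * 4), dim = c(8, 8, 1, 4))
  prof <- profile_model(m, batch, sparsity_config(batch_size = 4L))
  expect_identical(prof$layer_id, c("relu1", "relu2"))
  expect_true(all(prof$sparsity >= 0 & prof$sparsity <= 1))
  expect_match(attr(prof, "batch_fingerprint"), "^8x8x1x4\\|")
  expect_error(profile_model(m, batch, sparsity_config(batch_size = 16L)),
               "expects 16")
})

test_that("truncation with copied weights reproduces the prefix (fidelity)", {
  g <- tiny_graph(input_size = 8L)
  m <- init_model(g, seed = 5)
  x <- array(runif(8 * 8 * 1 * 3), dim = c(8, 8, 1, 3))
  full <- model_forward(m, x, keep_all = TRUE)
  cut <- truncate_at(m, "relu2")
  expect_s3_class(cut, "cnn_model")
  got <- model_forward(cut, x)$out
  expect_equal(got, full$cache$relu2$out, tolerance = 1e-12)
})

test_that("cuts inside an unmerged residual branch are rejected", {
  # Two parallel conv+relu branches merged by add: cutting either branch's
  # relu would silently drop the other branch's relu.
  g <- model_graph(list(
    layer_node("in", "input", params = list(shape = c(6, 6, 2))),
    layer_node("ca", "conv2d",
               params = list(filters = 2, kernel = 3, padding = "same"),
               preds = "in"),
    layer_node("ra", "relu_activation", preds = "ca"),
    layer_node("cb", "conv2d",
               params = list(filters = 2, kernel = 3, padding = "same"),
               preds = "in"),
    layer_node("rb", "relu_activation", preds = "cb"),
    layer_node("add", "add_merge", preds = c("ra", "rb")),
    layer_node("rm", "relu_activation", preds = "add"),
    layer_node("gap", "global_avg_pool", preds = "rm"),
    layer_node("fc", "dense", params = list(units = 2), preds = "gap"),
    layer_node("soft", "softmax", preds = "fc")
  ), "soft")
  err <- expect_error(truncate_at(g, "ra"), "unmerged residual branch")
  expect_match(conditionMessage(err), "rb")       # names the dropped relu
  expect_match(conditionMessage(err), "rm")       # nearest valid downstream
  # cutting after the merge is fine
  expect_s3_class(truncate_at(g, "rm"), "model_graph")
})

test_that("attach_classifier_head appends gap/dense/softmax", {
  g <- tiny_graph()
  backbone <- truncate_at(g, "relu2")
  h <- attach_classifier_head(backbone, 5)
  shp <- infer_shapes(h)
  expect_identical(shp[[h$output_id]], 5L)
  expect_identical(h$nodes[[h$output_id]]$kind, "softmax")
  expect_error(attach_classifier_head(h, 5), "not spatial")
  expect_error(attach_classifier_head(backbone, 1), ">= 2")
})

test_that("parameter counts decrease monotonically with shallower cuts", {
  g <- micro_graph()
  cuts <- c("block7_sepconv2_act", "block6_sepconv3_act",
            "block4_sepconv2_act", "block3_sepconv2_act")
  counts <- vapply(cuts, function(cut) {
    parameter_count(attach_classifier_head(truncate_at(g, cut), 7L))
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("separable backbones restrict cut candidates past the entry flow", {
  g <- micro_graph(input_size = 32L)
  m <- init_model(g, seed = 3)
  set.seed(4)
  batch <- array(stats::runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  prof <- profile_model(m, batch, sparsity_config(batch_size = 4L))
  # only activations downstream of the first identity-shortcut residual
  # merge, and never the backbone's last activation (a no-op cut)
  expect_identical(prof$layer_id,
                   c("block6_sepconv1_act", "block6_sepconv2_act",
                     "block6_sepconv3_act", "block7_sepconv1_act",
                     "block7_sepconv2_act", "block8_sepconv1_act"))
})
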