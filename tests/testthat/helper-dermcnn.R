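# Shared fixtures for the test suite.  Everything is generated in code.

# Published "No Sampling" per-class training counts (nv, mel, bkl, bcc,
# akiec, vasc, df).
table2_train_counts <- function() {
  c(nv = 5331, mel = 908, bkl = 872, bcc = 420, akiec = 272, vasc = 114,
    df = 95)
}

# The worked 3x3 pooling window from the pooling description.
worked_window <- function() {
  matrix(c(1, 5, 2,
           3, 8, 6,
           4, 7, 0), nrow = 3, byrow = TRUE)
}

# A micro Xception preset small enough for unit tests.
micro_graph <- function(input_size = 32L, n_classes = 7L) {
  build_xception(xception_config(input_size = input_size,
                                 n_classes = n_classes,
                                 width_multiplier = 0.125,
                                 middle_blocks = 2L))
}

# A small plain sequential conv net (conv -> relu -> pool -> conv -> relu ->
# GAP -> dense -> softmax) used where the full backbone is overkill.
tiny_graph <- function(input_size = 8L, channels = 1L, n_classes = 3L,
                       bn = FALSE) {
  bn_or_id <- function(nodes, id, pred) {
    if (bn) c(nodes, list(layer_node(id, "batch_norm", preds = pred)))
    else nodes
  }
  nodes <- list(
    layer_node("in", "input", params = list(shape = c(input_size, input_size,
                                                      channels))),
    layer_node("conv1", "conv2d", preds = "in",
               params = list(filters = 4L, kernel = 3L, stride = 1L,
                             padding = "same", use_bias = TRUE)))
  nodes <- bn_or_id(nodes, "bn1", "conv1")
  nodes <- c(nodes, list(
    layer_node("relu1", "relu_activation",
               preds = if (bn) "bn1" else "conv1"),
    layer_node("pool1", "max_pool", preds = "relu1",
               params = list(window = 2L, stride = 2L)),
    layer_node("conv2", "conv2d", preds = "pool1",
               params = list(filters = 6L, kernel = 3L, stride = 1L,
                             padding = "same", use_bias = TRUE))))
  nodes <- bn_or_id(nodes, "bn2", "conv2")
  model_graph(c(nodes, list(
    layer_node("relu2", "relu_activation",
               preds = if (bn) "bn2" else "conv2"),
    layer_node("gap", "global_avg_pool", preds = "relu2"),
    layer_node("fc", "dense", preds = "gap",
               params = list(units = n_classes)),
    layer_node("soft", "softmax", preds = "fc")
  )), output_id = "soft")
}

# Small synthetic dataset used across tests.
tiny_dataset <- function(n_per_class = c(12, 6, 4), image_size = 16L,
                         seed = 42L) {
  counts <- stats::setNames(n_per_class,
                            c("nv", "mel", "bkl")[seq_along(n_per_class)])
  generate_dataset(synthetic_spec(counts, image_size = image_size,
                                  seed = seed))
}

# Central-difference gradient of f at x.
numeric_gradient <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
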