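#' Xception backbone configuration
#'
#' Describes an Xception-style separable-convolution classifier: an entry
#' flow of strided blocks, `middle_blocks` residual middle-flow blocks, an
#' exit flow, and a global-average-pool + dense + softmax head.
#' `width_multiplier` scales every channel width; the "micro" preset
#' (`xception_micro_config()`) shrinks the network enough for fast CPU
#' experiments.
#'
#' @param input_size Input resolution in pixels (square images); must be
#'   >= 32 and divisible by 4.  Default 128.
#' @param n_classes Number of output classes (>= 2).  Default 7, the number
#'   of lesion categories in HAM10000-style dermoscopy data.
#' @param width_multiplier Fraction scaling all channel widths; every stage
#'   must keep at least one channel.
#' @param middle_blocks Number of middle-flow residual blocks (default 8).
#' @return An object of class `xception_config`.
#' @export
xception_config <- function(input_size = 128L, n_classes = 7L,
                            width_multiplier = 1.0, middle_blocks = 8L) {
  input_size <- as.integer(input_size)
  if (input_size < 32L || input_size %% 4L != 0L) {
    stop("input_size must be >= 32 and divisible by 4")
  }
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  if (middle_blocks < 0L) stop("middle_blocks must be >= 0")
  structure(list(input_size = input_size, n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier,
                 middle_blocks = as.integer(middle_blocks)),
            class = "xception_config")
}

#' Micro Xception preset
#'
#' A width-0.125, two-middle-block, 32-pixel variant used throughout the
#' test-suite and desk-scale pipelines: the same topology as the full
#' backbone (entry/middle/exit flows, residual shortcuts, max pools) at a
#' size where forward passes take milliseconds on one CPU.
#'
#' @param input_size Input resolution (default 32).
#' @param n_classes Number of classes (default 7).
#' @return An `xception_config`.
#' @export
xception_micro_config <- function(input_size = 32L, n_classes = 7L) {
  xception_config(input_size = input_size, n_classes = n_classes,
                  width_multiplier = 0.125, middle_blocks = 2L)
}

xception_width <- function(base, multiplier) {
  ch <- as.integer(round(base * multiplier))
  if (ch < 1L) {
    stop(sprintf("width_multiplier %.4g collapses a %d-channel stage to 0 channels",
                 multiplier, base))
  }
  ch
}

#' Build an Xception-style model graph
#'
#' Constructs the layer DAG of the backbone plus classifier head.  Node ids
#' follow the conventional `blockN_sepconvM` / `blockN_sepconvM_act` naming
#' (with `_act` marking ReLU outputs), so sparsity-profile cut points are
#' addressable by name; with the default eight middle blocks the deepest
#' middle block is `block12` and the exit flow is `block13`/`block14`.
#' Separable and standard convolutions carry no bias (each is followed by
#' batch normalisation); the dense head carries a bias.
#'
#' @param config An [xception_config()].
#' @return A [model_graph()] ending in `softmax`.
#' @export
build_xception <- function(config) {
  stopifnot(inherits(config, "xception_config"))
  w <- config$width_multiplier
  ch <- function(base) xception_width(base, w)
  nodes <- list()
  add <- function(id, kind, params = list(), preds) {
    nodes[[length(nodes) + 1L]] <<- layer_node(id, kind, params, preds)
    id
  }
  sepconv <- function(id, filters, from) {
    x <- add(id, "separable_conv2d",
             list(kernel = 3L, filters = filters, stride = 1L,
                  padding = "same", use_bias = FALSE), from)
    add(paste0(id, "_bn"), "batch_norm", preds = x)
  }

  x <- add("input", "input",
           list(shape = c(config$input_size, config$input_size, 3L)),
           character())

  # entry flow
  x <- add("block1_conv1", "conv2d",
           list(kernel = 3L, filters = ch(32), stride = 2L, padding = "valid",
                use_bias = FALSE), x)
  x <- add("block1_conv1_bn", "batch_norm", preds = x)
  x <- add("block1_conv1_act", "relu_activation", preds = x)
  x <- add("block1_conv2", "conv2d",
           list(kernel = 3L, filters = ch(64), stride = 1L, padding = "valid",
                use_bias = FALSE), x)
  x <- add("block1_conv2_bn", "batch_norm", preds = x)
  x <- add("block1_conv2_act", "relu_activation", preds = x)

  entry_block <- function(block, filters, x, leading_act) {
    res <- add(sprintf("block%d_res_conv", block), "conv2d",
               list(kernel = 1L, filters = filters, stride = 2L,
                    padding = "same", use_bias = FALSE), x)
    res <- add(sprintf("block%d_res_bn", block), "batch_norm", preds = res)
    h <- x
    if (leading_act) {
      h <- add(sprintf("block%d_sepconv1_act", block), "relu_activation", preds = h)
    }
    h <- sepconv(sprintf("block%d_sepconv1", block), filters, h)
    h <- add(sprintf("block%d_sepconv2_act", block), "relu_activation", preds = h)
    h <- sepconv(sprintf("block%d_sepconv2", block), filters, h)
    h <- add(sprintf("block%d_pool", block), "max_pool",
             list(window = 3L, stride = 2L, padding = "same"), h)
    add(sprintf("block%d_add", block), "add_merge", preds = c(h, res))
  }
  x <- entry_block(2L, ch(128), x, leading_act = FALSE)
  x <- entry_block(3L, ch(256), x, leading_act = TRUE)
  x <- entry_block(4L, ch(728), x, leading_act = TRUE)

  # middle flow
  mid <- ch(728)
  for (b in seq_len(config$middle_blocks) + 4L) {
    res <- x
    h <- x
    for (m in 1:3) {
      h <- add(sprintf("block%d_sepconv%d_act", b, m), "relu_activation", preds = h)
      h <- sepconv(sprintf("block%d_sepconv%d", b, m), mid, h)
    }
    x <- add(sprintf("block%d_add", b), "add_merge", preds = c(h, res))
  }

  # exit flow
  b13 <- config$middle_blocks + 5L
  b14 <- config$middle_blocks + 6L
  res <- add(sprintf("block%d_res_conv", b13), "conv2d",
             list(kernel = 1L, filters = ch(1024), stride = 2L,
                  padding = "same", use_bias = FALSE), x)
  res <- add(sprintf("block%d_res_bn", b13), "batch_norm", preds = res)
  h <- add(sprintf("block%d_sepconv1_act", b13), "relu_activation", preds = x)
  h <- sepconv(sprintf("block%d_sepconv1", b13), ch(728), h)
  h <- add(sprintf("block%d_sepconv2_act", b13), "relu_activation", preds = h)
  h <- sepconv(sprintf("block%d_sepconv2", b13), ch(1024), h)
  h <- add(sprintf("block%d_pool", b13), "max_pool",
           list(window = 3L, stride = 2L, padding = "same"), h)
  x <- add(sprintf("block%d_add", b13), "add_merge", preds = c(h, res))

  x <- sepconv(sprintf("block%d_sepconv1", b14), ch(1536), x)
  x <- add(sprintf("block%d_sepconv1_act", b14), "relu_activation", preds = x)
  x <- sepconv(sprintf("block%d_sepconv2", b14), ch(2048), x)
  x <- add(sprintf("block%d_sepconv2_act", b14), "relu_activation", preds = x)

  # head
  x <- add("avg_pool", "global_avg_pool", preds = x)
  x <- add("predictions", "dense",
           list(units = config$n_classes, use_bias = TRUE), x)
  x <- add("softmax", "softmax", preds = x)

  model_graph(nodes, x)
}
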