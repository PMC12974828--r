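#' Pooling specification
#'
#' Describes a 2-D pooling operation: an `n x n` window slid with `stride`,
#' retaining the mean of the `K` largest values per window (Avg-TopK).
#' `K = 1` reproduces max pooling and `K = window^2` reproduces average
#' pooling.  Under `"same"` padding, padded positions are excluded from the
#' ranking and `K` is clamped to the number of real elements in the window.
#'
#' @param window Window side length (positive integer).
#' @param stride Stride (positive integer, default `window`).
#' @param K Number of top values averaged (default 3).
#' @param padding `"valid"` (default) or `"same"`.
#' @return An object of class `pooling_spec`.
#' @export
pooling_spec <- function(window, stride = window, K = 3L, padding = "valid") {
  window <- as.integer(window); stride <- as.integer(stride); K <- as.integer(K)
  if (window < 1L || stride < 1L || K < 1L) {
    stop("window, stride and K must be positive integers")
  }
  padding <- match.arg(padding, c("valid", "same"))
  structure(list(window = window, stride = stride, K = K, padding = padding),
            class = "pooling_spec")
}

#' Mean of the K largest values
#'
#' The scalar core of Avg-TopK pooling: sorts the window values in
#' non-increasing order and averages the first `K` (clamped to the number of
#' values present).  With the worked 3x3 window `1,5,2,3,8,6,4,7,0` and
#' `K = 3` this yields `(8 + 7 + 6) / 3 = 7`; `K = 1` gives the max pooling
#' result 8 and `K = 9` the average pooling result 4.
#'
#' @param values Non-empty numeric vector (the pooling-window contents).
#' @param K Positive integer.
#' @return The mean of the `min(K, length(values))` largest values.
#' @export
topk_mean <- function(values, K) {
  if (length(values) == 0L) stop("topk_mean: empty input")
  if (K < 1L) stop("topk_mean: K must be >= 1")
  k <- min(as.integer(K), length(values))
  # decreasing stable sort; ties resolved by original scan order
  mean(values[order(-values)][seq_len(k)])
}

#' Avg-TopK pooling over a feature map
#'
#' Applies [topk_mean()] per channel and per window across a spatial feature
#' map, caching which positions were selected so the backward pass can route
#' gradients.  Ties at the K-th value are broken by row-major scan order.
#'
#' @param feature_map Array `(H, W, C)` or batch `(H, W, C, N)`.
#' @param spec A [pooling_spec()].
#' @return The pooled array (same dimensionality as the input), with
#'   attribute `"cache"` holding the selection record used by
#'   [avg_topk_backward()].
#' @export
avg_topk_pool2d <- function(feature_map, spec) {
  stopifnot(inherits(spec, "pooling_spec"))
  d <- dim(feature_map)
  squeeze <- FALSE
  if (length(d) == 3L) {
    dim(feature_map) <- c(d, 1L)
    squeeze <- TRUE
  } else if (length(d) != 4L) {
    stop("feature_map must be (H, W, C) or (H, W, C, N)")
  }
  if (spec$padding == "valid" &&
      (dim(feature_map)[1] < spec$window || dim(feature_map)[2] < spec$window)) {
    stop(sprintf("window %d larger than %dx%d input under valid padding",
                 spec$window, dim(feature_map)[1], dim(feature_map)[2]))
  }
  r <- .avgtopk_fw(feature_map, spec$window, spec$stride, spec$K,
                   spec$padding == "same")
  y <- r$y
  cache <- list(sel = r$sel, in_dim = dim(feature_map), squeeze = squeeze)
  if (squeeze) {
    dy <- dim(y)
    dim(y) <- dy[1:3]
  }
  attr(y, "cache") <- cache
  y
}

#' Backward pass of Avg-TopK pooling
#'
#' Each position selected in the forward pass receives `upstream / K_eff`
#' (uniform routing, the exact gradient of the top-K mean away from ties);
#' unselected positions receive zero and overlapping windows accumulate.
#'
#' @param upstream_gradient Gradient w.r.t. the pooled output (same shape as
#'   the forward output).
#' @param cache The `"cache"` attribute produced by [avg_topk_pool2d()].
#' @return Gradient w.r.t. the input feature map.
#' @export
avg_topk_backward <- function(upstream_gradient, cache) {
  if (is.null(cache$sel) || is.null(cache$in_dim)) {
    stop("invalid or missing forward cache")
  }
  if (length(upstream_gradient) != ncol(cache$sel)) {
    stop("upstream gradient shape does not match the cached forward pass")
  }
  dx <- .avgtopk_bw(as.numeric(upstream_gradient), cache$sel,
                    as.integer(cache$in_dim))
  if (isTRUE(cache$squeeze)) dim(dx) <- cache$in_dim[1:3]
  dx
}

#' Replace max pooling with Avg-TopK pooling
#'
#' Graph surgery: every `max_pool` node becomes an `avg_topk_pool` node with
#' identical window, stride and padding and the given `K`; all other nodes
#' are untouched.  The input graph is not modified.
#'
#' @param graph A [model_graph()].
#' @param K Number of top values to average (default 3).
#' @return A new [model_graph()] containing no `max_pool` nodes.
#' @export
replace_max_pooling <- function(graph, K = 3L) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  n_pool <- sum(vapply(graph$nodes, function(n) n$kind == "max_pool", logical(1)))
  if (n_pool == 0L) {
    message("replace_max_pooling: graph contains no max_pool nodes; returned unchanged")
    return(graph)
  }
  nodes <- lapply(graph$nodes, function(n) {
    if (n$kind != "max_pool") return(n)
    layer_node(n$id, "avg_topk_pool",
               params = list(window = n$params$window,
                             stride = n$params$stride %||% 1L,
                             K = K,
                             padding = n$params$padding %||% "valid"),
               preds = n$preds)
  })
  model_graph(nodes, graph$output_id)
}
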