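#' @useDynLib dermcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail modifyList
NULL

LAYER_KINDS <- c(
  "input", "conv2d", "separable_conv2d", "batch_norm", "relu_activation",
  "max_pool", "avg_topk_pool", "global_avg_pool", "add_merge", "dense",
  "softmax", "flatten", "dropout"
)

#' Create a layer node
#'
#' A layer node is one vertex of a [model_graph()]: a typed layer with
#' kind-specific hyperparameters and a list of predecessor node ids.
#'
#' @param id Unique node id (non-empty string).
#' @param kind One of `r paste0('"', LAYER_KINDS, '"', collapse = ", ")`.
#' @param params Named list of kind-specific hyperparameters (e.g. `kernel`,
#'   `filters`, `stride`, `padding`, `window`, `K`, `units`, `rate`,
#'   `use_bias`, and `shape` for the input node).
#' @param preds Character vector of predecessor node ids (empty only for the
#'   input node).
#' @return An object of class `layer_node`.
#' @export
layer_node <- function(id, kind, params = list(), preds = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("node id must be a non-empty string")
  }
  kind <- match.arg(kind, LAYER_KINDS)
  if (kind == "input") {
    if (length(preds) != 0L) stop("input node must have no predecessors")
    shp <- params$shape
    if (is.null(shp) || length(shp) != 3L || any(shp < 1)) {
      stop("input node requires params$shape = c(H, W, C)")
    }
    params$shape <- as.integer(shp)
  } else if (length(preds) < 1L) {
    stop(sprintf("non-input node '%s' must have at least one predecessor", id))
  }
  if (kind == "add_merge" && length(preds) < 2L) {
    stop(sprintf("add_merge node '%s' needs >= 2 predecessors", id))
  }
  for (f in c("kernel", "filters", "stride", "window", "K", "units")) {
    if (!is.null(params[[f]])) {
      v <- params[[f]]
      if (length(v) != 1L || is.na(v) || v < 1 || v != round(v)) {
        stop(sprintf("node '%s': %s must be a positive integer", id, f))
      }
      params[[f]] <- as.integer(v)
    }
  }
  if (!is.null(params$padding)) {
    params$padding <- match.arg(params$padding, c("valid", "same"))
  }
  if (!is.null(params$use_bias)) params$use_bias <- isTRUE(params$use_bias)
  if (!is.null(params$rate)) {
    if (params$rate < 0 || params$rate >= 1) stop("dropout rate must be in [0, 1)")
    params$rate <- as.numeric(params$rate)
  }
  structure(list(id = id, kind = kind, params = params,
                 preds = as.character(preds)),
            class = "layer_node")
}

#' Create a model graph
#'
#' A model graph is a DAG of [layer_node()]s stored in a fixed, deterministic
#' topological order (the construction order, validated so that every
#' predecessor appears before its consumers).  Exactly one `input` node is
#' required and `output_id` names the graph output.
#'
#' @param nodes List of `layer_node` objects in topological order.
#' @param output_id Id of the output node.
#' @return An object of class `model_graph`.
#' @export
model_graph <- function(nodes, output_id) {
  ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate node ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(nodes) <- ids
  kinds <- vapply(nodes, function(n) n$kind, character(1))
  if (sum(kinds == "input") != 1L) stop("graph must contain exactly one input node")
  seen <- character(0)
  for (n in nodes) {
    missing <- setdiff(n$preds, seen)
    if (length(missing)) {
      stop(sprintf("node '%s' references predecessor(s) not defined earlier: %s",
                   n$id, paste(missing, collapse = ", ")))
    }
    seen <- c(seen, n$id)
  }
  if (!output_id %in% ids) stop(sprintf("output node '%s' not in graph", output_id))
  g <- structure(list(nodes = nodes, output_id = output_id),
                 class = "model_graph")
  infer_shapes(g)  # fails loudly on dangling / inconsistent shapes
  g
}

#' @export
print.model_graph <- function(x, ...) {
  shp <- infer_shapes(x)
  cat(sprintf("<model_graph> %d nodes, output '%s', %s parameters\n",
              length(x$nodes), x$output_id,
              format(parameter_count(x), big.mark = ",")))
  cat(sprintf("  output shape: [%s]\n",
              paste(shp[[x$output_id]], collapse = "x")))
  invisible(x)
}

node_ids <- function(graph) names(graph$nodes)

get_node <- function(graph, id) {
  n <- graph$nodes[[id]]
  if (is.null(n)) stop(sprintf("unknown node id '%s'", id))
  n
}

input_id <- function(graph) {
  kinds <- vapply(graph$nodes, function(n) n$kind, character(1))
  names(graph$nodes)[kinds == "input"]
}

successor_map <- function(graph) {
  succ <- setNames(vector("list", length(graph$nodes)), node_ids(graph))
  for (n in graph$nodes) {
    for (p in n$preds) succ[[p]] <- c(succ[[p]], n$id)
  }
  succ
}

pool_out_size <- function(size, k, stride, padding) {
  if (padding == "same") {
    as.integer(ceiling(size / stride))
  } else {
    if (size < k) {
      stop(sprintf("spatial size %d smaller than window/kernel %d under valid padding",
                   size, k))
    }
    as.integer((size - k) %/% stride + 1L)
  }
}

#' Infer per-node output shapes
#'
#' Propagates shapes from the input node through the graph.  Spatial layers
#' have shape `c(H, W, C)`; `global_avg_pool`, `flatten`, `dense` and
#' `softmax` produce flat shapes `c(F)`.
#'
#' @param graph A [model_graph()].
#' @return Named list mapping node id to its output shape (integer vector).
#' @export
infer_shapes <- function(graph) {
  shapes <- list()
  for (n in graph$nodes) {
    shapes[[n$id]] <- switch(
      n$kind,
      input = n$params$shape,
      conv2d = {
        s <- shapes[[n$preds[1]]]
        if (length(s) != 3L) stop(sprintf("conv2d '%s' needs a spatial input", n$id))
        c(pool_out_size(s[1], n$params$kernel, n$params$stride %||% 1L, n$params$padding %||% "valid"),
          pool_out_size(s[2], n$params$kernel, n$params$stride %||% 1L, n$params$padding %||% "valid"),
          n$params$filters)
      },
      separable_conv2d = {
        s <- shapes[[n$preds[1]]]
        if (length(s) != 3L) stop(sprintf("separable_conv2d '%s' needs a spatial input", n$id))
        c(pool_out_size(s[1], n$params$kernel, n$params$stride %||% 1L, n$params$padding %||% "same"),
          pool_out_size(s[2], n$params$kernel, n$params$stride %||% 1L, n$params$padding %||% "same"),
          n$params$filters)
      },
      batch_norm = shapes[[n$preds[1]]],
      relu_activation = shapes[[n$preds[1]]],
      dropout = shapes[[n$preds[1]]],
      max_pool = ,
      avg_topk_pool = {
        s <- shapes[[n$preds[1]]]
        if (length(s) != 3L) stop(sprintf("pool '%s' needs a spatial input", n$id))
        c(pool_out_size(s[1], n$params$window, n$params$stride %||% 1L, n$params$padding %||% "valid"),
          pool_out_size(s[2], n$params$window, n$params$stride %||% 1L, n$params$padding %||% "valid"),
          s[3])
      },
      global_avg_pool = {
        s <- shapes[[n$preds[1]]]
        if (length(s) != 3L) stop(sprintf("global_avg_pool '%s' needs a spatial input", n$id))
        s[3]
      },
      flatten = {
        s <- shapes[[n$preds[1]]]
        as.integer(prod(s))
      },
      add_merge = {
        ps <- lapply(n$preds, function(p) shapes[[p]])
        for (i in seq_along(ps)[-1]) {
          if (!identical(ps[[1]], ps[[i]])) {
            stop(sprintf("add_merge '%s': predecessor shapes differ ([%s] vs [%s])",
                         n$id, paste(ps[[1]], collapse = "x"),
                         paste(ps[[i]], collapse = "x")))
          }
        }
        ps[[1]]
      },
      dense = {
        s <- shapes[[n$preds[1]]]
        if (length(s) != 1L) stop(sprintf("dense '%s' needs a flat input; add flatten or global_avg_pool", n$id))
        n$params$units
      },
      softmax = {
        s <- shapes[[n$preds[1]]]
        if (length(s) != 1L) stop(sprintf("softmax '%s' needs a flat input", n$id))
        s
      },
      stop(sprintf("shape inference: unhandled kind '%s'", n$kind))
    )
    shapes[[n$id]] <- as.integer(shapes[[n$id]])
  }
  shapes
}

node_parameter_count <- function(node, in_shape) {
  bias <- isTRUE(node$params$use_bias)
  switch(
    node$kind,
    conv2d = {
      cin <- in_shape[3]
      node$params$kernel^2 * cin * node$params$filters +
        if (bias) node$params$filters else 0L
    },
    separable_conv2d = {
      cin <- in_shape[3]
      node$params$kernel^2 * cin + cin * node$params$filters +
        if (bias) node$params$filters else 0L
    },
    batch_norm = 4L * in_shape[length(in_shape)],
    dense = in_shape[1] * node$params$units +
      if (isTRUE(node$params$use_bias) || is.null(node$params$use_bias)) node$params$units else 0L,
    0L
  )
}

#' Count trainable and tracked parameters
#'
#' Sums closed-form per-layer counts: a separable convolution contributes
#' `k^2 * C_in + C_in * C_out` (+ bias), a standard convolution
#' `k^2 * C_in * C_out` (+ bias), batch normalisation `4 * C` (scale, shift
#' and the two running moments), a dense layer `in * out + out`; all other
#' kinds are parameterless.
#'
#' @param graph A [model_graph()].
#' @return Integer-valued numeric scalar.
#' @export
parameter_count <- function(graph) {
  shapes <- infer_shapes(graph)
  total <- 0
  for (n in graph$nodes) {
    in_shape <- if (length(n$preds)) shapes[[n$preds[1]]] else NULL
    cnt <- node_parameter_count(n, in_shape)
    if (is.null(cnt) || anyNA(cnt)) {
      stop(sprintf("cannot count parameters of node '%s' (uninferable shape)", n$id))
    }
    total <- total + cnt
  }
  total
}

#' Ancestor set of a node
#'
#' All nodes lying on some path from the input to `node_id`, including
#' `node_id` itself.
#'
#' @param graph A [model_graph()].
#' @param node_id Node id.
#' @return Character vector of node ids in the graph's topological order.
#' @export
ancestors <- function(graph, node_id) {
  get_node(graph, node_id)
  anc <- new.env(parent = emptyenv())
  visit <- function(id) {
    if (!is.null(anc[[id]])) return(invisible())
    anc[[id]] <- TRUE
    for (p in graph$nodes[[id]]$preds) visit(p)
  }
  visit(node_id)
  ids <- node_ids(graph)
  ids[ids %in% ls(anc)]
}

descendants <- function(graph, node_id) {
  get_node(graph, node_id)
  succ <- successor_map(graph)
  dec <- new.env(parent = emptyenv())
  visit <- function(id) {
    if (!is.null(dec[[id]])) return(invisible())
    dec[[id]] <- TRUE
    for (s in succ[[id]]) visit(s)
  }
  visit(node_id)
  ids <- node_ids(graph)
  ids[ids %in% ls(dec)]
}

#' Serialize a model graph to JSON
#'
#' Writes the graph as a JSON document `{"nodes": [...], "output_id": ...}`
#' with stable key order; [graph_from_json()] restores it losslessly.
#'
#' @param graph A [model_graph()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
graph_to_json <- function(graph, path = NULL) {
  nodes <- lapply(graph$nodes, function(n) {
    list(id = n$id, kind = n$kind,
         params = n$params[order(names(n$params) %||% character())],
         preds = as.list(n$preds))
  })
  names(nodes) <- NULL
  js <- jsonlite::toJSON(list(nodes = nodes, output_id = graph$output_id),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a model graph from JSON
#'
#' @param json JSON string or path to a JSON file written by [graph_to_json()].
#' @return A [model_graph()].
#' @export
graph_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  nodes <- lapply(doc$nodes, function(n) {
    params <- n$params
    if (!is.null(params$shape)) params$shape <- unlist(params$shape)
    layer_node(n$id, n$kind, params = params, preds = unlist(n$preds) %||% character())
  })
  model_graph(nodes, doc$output_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
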