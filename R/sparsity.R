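#' Sparsity-profiling configuration
#'
#' @param batch_size Number of validation images used for profiling
#'   (default 16).
#' @param zero_tolerance Absolute threshold below which an activation counts
#'   as zero (default 0: ReLU emits exact zeros).
#' @param candidate_kinds Layer kinds eligible for profiling; by default only
#'   post-ReLU outputs, matching the convention that cut points are `*_act`
#'   layers.
#' @return An object of class `sparsity_config`.
#' @export
sparsity_config <- function(batch_size = 16L, zero_tolerance = 0,
                            candidate_kinds = "relu_activation") {
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (zero_tolerance < 0) stop("zero_tolerance must be >= 0")
  structure(list(batch_size = batch_size, zero_tolerance = zero_tolerance,
                 candidate_kinds = candidate_kinds),
            class = "sparsity_config")
}

#' Batch-averaged activation sparsity
#'
#' The per-layer importance signal: the fraction of (near-)zero elements in
#' each sample's activation, averaged over the batch,
#' `S = (1/B) * sum_b #\{|a| <= tol\} / |a_b|`.
#'
#' @param batch_activations List of per-sample activation arrays (all the
#'   same shape), or a single array whose last dimension indexes samples.
#' @param tolerance Absolute zero threshold (default 0).
#' @return Sparsity in `[0, 1]`.
#' @export
activation_sparsity <- function(batch_activations, tolerance = 0) {
  if (is.array(batch_activations) || is.matrix(batch_activations)) {
    d <- dim(batch_activations)
    nb <- d[length(d)]
    m <- matrix(batch_activations, ncol = nb)
    batch_activations <- lapply(seq_len(nb), function(b) m[, b])
  }
  if (length(batch_activations) == 0L) stop("empty activation batch")
  fracs <- vapply(batch_activations,
                  function(a) mean(abs(a) <= tolerance), numeric(1))
  mean(fracs)
}

#' Profile activation sparsity over a model
#'
#' Runs the profiling batch through the network (inference mode: batch norm
#' uses its running moments, no dropout) and records the batch-averaged
#' sparsity of every candidate layer, in topological order.
#'
#' In separable-convolution backbones, candidates are further restricted to
#' activations downstream of the first identity-shortcut residual merge:
#' the entry flow (stem and strided projection-shortcut blocks) is the
#' generic feature extractor and is never a cut point.  Activations with no
#' convolutional descendants are also excluded, since cutting there removes
#' nothing.  On the full-scale backbone these restrictions yield exactly
#' the published candidate set.
#'
#' @param model A [init_model()] object.
#' @param batch Array `(H, W, C, B)` of preprocessed validation images.
#' @param config A [sparsity_config()].
#' @return An object of class `sparsity_profile`: a data.frame with columns
#'   `layer_id` and `sparsity`, plus a `batch_fingerprint` attribute.
#' @export
profile_model <- function(model, batch, config = sparsity_config()) {
  stopifnot(inherits(config, "sparsity_config"))
  if (length(dim(batch)) == 3L) dim(batch) <- c(dim(batch), 1L)
  if (dim(batch)[4] != config$batch_size) {
    stop(sprintf("profiling batch has %d images, config expects %d",
                 dim(batch)[4], config$batch_size))
  }
  cand <- names(model$graph$nodes)[vapply(model$graph$nodes, function(n)
    n$kind %in% config$candidate_kinds, logical(1))]
  cand <- intersect(ancestors(model$graph, model$graph$output_id), cand)
  # In separable-convolution backbones the cut candidates are restricted to
  # activations past the entry feature extractor: every published cut point
  # is a sepconv activation downstream of the first identity-shortcut
  # residual block (the entry flow, whose residual shortcuts are all strided
  # projections, is never pruned).  Plain-convolution networks are
  # unaffected.
  has_sep <- any(vapply(model$graph$nodes, function(n)
    n$kind == "separable_conv2d", logical(1)))
  if (has_sep) {
    cand <- cand[vapply(cand, function(id) {
      anc <- ancestors(model$graph, id)
      any(vapply(model$graph$nodes[anc], function(n)
        n$kind == "separable_conv2d", logical(1)))
    }, logical(1))]
    merges <- names(model$graph$nodes)[vapply(model$graph$nodes, function(n)
      n$kind == "add_merge", logical(1))]
    id_merges <- merges[vapply(merges, function(m) {
      p <- model$graph$nodes[[m]]$preds
      length(p) == 2L && (p[1] %in% ancestors(model$graph, p[2]) ||
                          p[2] %in% ancestors(model$graph, p[1]))
    }, logical(1))]
    if (length(id_merges)) {
      past <- unique(unlist(lapply(id_merges, function(m)
        descendants(model$graph, m))))
      cand <- cand[cand %in% past]
    }
    # a cut must remove at least one convolutional layer; cutting at the
    # backbone's last activation would be a no-op
    cand <- cand[vapply(cand, function(id) {
      dec <- setdiff(descendants(model$graph, id), id)
      any(vapply(model$graph$nodes[dec], function(n)
        n$kind %in% c("conv2d", "separable_conv2d"), logical(1)))
    }, logical(1))]
  }
  if (length(cand) == 0L) {
    stop("graph has no candidate layers of kind: ",
         paste(config$candidate_kinds, collapse = ", "))
  }
  fw <- model_forward(model, batch, training = FALSE, keep_all = TRUE)
  sparsity <- vapply(cand, function(id)
    activation_sparsity(fw$cache[[id]]$out, config$zero_tolerance), numeric(1))
  prof <- data.frame(layer_id = cand, sparsity = unname(sparsity),
                     stringsAsFactors = FALSE)
  attr(prof, "batch_fingerprint") <- sprintf(
    "%s|%.10e|%.10e", paste(dim(batch), collapse = "x"),
    sum(batch), sum(batch * batch))
  class(prof) <- c("sparsity_profile", class(prof))
  prof
}

#' Select the pruning cut from a sparsity profile
#'
#' Returns the layer with maximal sparsity; ties are broken by the earliest
#' topological position (the more aggressive cut).
#'
#' @param profile A [profile_model()] result, or any data.frame with
#'   `layer_id` and `sparsity` columns in topological order.
#' @return The selected layer id (string).
#' @export
select_cut <- function(profile) {
  if (nrow(profile) == 0L) stop("empty sparsity profile")
  if (any(profile$sparsity < 0 | profile$sparsity > 1)) {
    stop("sparsity values must lie in [0, 1]")
  }
  profile$layer_id[which.max(profile$sparsity)]
}

# Parallel set of a cut: nodes that are neither ancestors nor descendants of
# it.  Truncation drops them; dropping a parallel ReLU would mean the cut
# sits on a residual shortcut branch and discards the main trunk.
cut_parallel_nodes <- function(graph, cut_layer_id) {
  setdiff(node_ids(graph),
          union(ancestors(graph, cut_layer_id), descendants(graph, cut_layer_id)))
}

valid_cut_points <- function(graph) {
  ids <- node_ids(graph)
  acts <- ids[vapply(graph$nodes, function(n) n$kind == "relu_activation",
                     logical(1))]
  acts[vapply(acts, function(id) {
    par <- cut_parallel_nodes(graph, id)
    !any(vapply(graph$nodes[par], function(n) n$kind == "relu_activation",
                logical(1)))
  }, logical(1))]
}

#' Truncate a model graph at a cut layer
#'
#' Keeps the induced subgraph on the ancestors of `cut_layer_id` and makes
#' the cut layer the new output; everything downstream (including the
#' classifier head) is removed.  Branches running in parallel with the cut
#' (e.g. an unmerged residual shortcut convolution) are dropped; if such a
#' branch contains an activation layer the cut is rejected as lying inside
#' an unmerged residual branch, and the error lists the nearest valid cut
#' points upstream and downstream.
#'
#' @param x A [model_graph()] or a `cnn_model` (whose kept weights are then
#'   copied verbatim).
#' @param cut_layer_id Id of the new output layer.
#' @return An object of the same class as `x`.
#' @export
truncate_at <- function(x, cut_layer_id) {
  graph <- if (inherits(x, "cnn_model")) x$graph else x
  node <- get_node(graph, cut_layer_id)
  if (node$kind == "input") stop("cannot truncate at the input node")
  par <- cut_parallel_nodes(graph, cut_layer_id)
  par_act <- par[vapply(graph$nodes[par], function(n)
    n$kind == "relu_activation", logical(1))]
  if (length(par_act)) {
    valid <- valid_cut_points(graph)
    pos <- match(node_ids(graph), node_ids(graph))
    here <- match(cut_layer_id, node_ids(graph))
    vpos <- match(valid, node_ids(graph))
    up <- valid[vpos < here]
    down <- valid[vpos > here]
    stop(sprintf(paste0(
      "invalid cut '%s': it lies inside an unmerged residual branch ",
      "(parallel activation layers %s would be dropped); nearest valid cut ",
      "points: upstream %s, downstream %s"),
      cut_layer_id, paste(par_act, collapse = ", "),
      if (length(up)) tail(up, 1) else "<none>",
      if (length(down)) down[1] else "<none>"))
  }
  keep <- ancestors(graph, cut_layer_id)
  pruned <- model_graph(graph$nodes[keep], cut_layer_id)
  if (inherits(x, "cnn_model")) {
    w <- x$weights[intersect(names(x$weights), keep)]
    structure(list(graph = pruned, weights = w,
                   shapes = infer_shapes(pruned)),
              class = "cnn_model")
  } else {
    pruned
  }
}

#' Attach a classifier head to a backbone
#'
#' Appends `global_avg_pool` + `dense(n_classes)` + `softmax` after the
#' current (spatial) output.
#'
#' @param graph A [model_graph()] with a spatial output.
#' @param n_classes Number of classes.
#' @return A new [model_graph()] ending in softmax.
#' @export
attach_classifier_head <- function(graph, n_classes) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  shp <- infer_shapes(graph)[[graph$output_id]]
  if (length(shp) != 3L) {
    stop(sprintf("output '%s' is not spatial; a classifier head is already attached or the graph ends in a flat layer",
                 graph$output_id))
  }
  nodes <- graph$nodes
  add_id <- function(base) {
    id <- base
    i <- 1L
    while (id %in% names(nodes)) { id <- sprintf("%s_%d", base, i); i <- i + 1L }
    id
  }
  gap <- add_id("avg_pool")
  dense <- add_id("predictions")
  soft <- add_id("softmax")
  nodes[[gap]] <- layer_node(gap, "global_avg_pool", preds = graph$output_id)
  nodes[[dense]] <- layer_node(dense, "dense",
                               list(units = n_classes, use_bias = TRUE),
                               preds = gap)
  nodes[[soft]] <- layer_node(soft, "softmax", preds = dense)
  model_graph(nodes, soft)
}

#' Prune by activation sparsity and retrain from scratch
#'
#' The full pruning procedure: profile candidate layers on a validation
#' batch, cut at the maximal-sparsity layer, truncate the graph, reattach a
#' fresh classifier head, re-initialise all weights and retrain.  Retraining
#' starts from scratch by default ("retrain from scratch"); set
#' `inherit_weights = TRUE` to fine-tune the kept backbone weights instead.
#'
#' @param model A trained [init_model()] object ending in softmax.
#' @param train_set A [labeled_image_set()] (training split only).
#' @param val_batch Array `(H, W, C, B)` of preprocessed validation images
#'   used for profiling (B = `sparsity_cfg$batch_size`).
#' @param sparsity_cfg A [sparsity_config()].
#' @param train_cfg A [train_config()].
#' @param inherit_weights Keep the backbone weights of the kept prefix
#'   instead of re-initialising (default `FALSE`).
#' @return List with `model` (trained pruned model), `history` (training
#'   history), `profile`, and `result` (a `prune_result` with
#'   `cut_layer_id`, `parameters_before`, `parameters_after`).
#' @export
prune_and_retrain <- function(model, train_set, val_batch,
                              sparsity_cfg = sparsity_config(),
                              train_cfg = train_config(),
                              inherit_weights = FALSE) {
  profile <- profile_model(model, val_batch, sparsity_cfg)
  cut <- select_cut(profile)
  n_classes <- length(train_set$class_names)
  before <- parameter_count(model$graph)
  backbone <- truncate_at(model$graph, cut)
  pruned_graph <- attach_classifier_head(backbone, n_classes)
  after <- parameter_count(pruned_graph)
  pruned <- init_model(pruned_graph, seed = train_cfg$seed)
  if (inherit_weights) {
    keep <- intersect(names(model$weights), names(backbone$nodes))
    pruned$weights[keep] <- model$weights[keep]
  }
  trained <- train_model(pruned, train_set, train_cfg)
  result <- structure(list(cut_layer_id = cut,
                           parameters_before = before,
                           parameters_after = after),
                      class = "prune_result")
  list(model = trained$model, history = trained$history,
       profile = profile, result = result)
}
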