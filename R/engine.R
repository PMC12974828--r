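# CNN execution engine: weight initialisation, forward pass (with per-node
# activation capture), reverse-mode gradients, and an Adam update step.
# Feature maps are arrays (H, W, C, N); flat activations are matrices (N, F).

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

glorot_uniform <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

#' Initialise a CNN model from a graph
#'
#' Allocates weights for every parameterised node (Glorot-uniform for
#' convolution and dense kernels; batch-norm scale one, shift zero, and
#' zero-initialised bias-corrected running moments) and returns a runnable
#' model object.
#'
#' @param graph A [model_graph()] whose output is a `softmax` node (for
#'   training) or any node (for feature extraction).
#' @param seed Integer seed controlling the initial weights.
#' @return An object of class `cnn_model` with fields `graph`, `weights`
#'   (named per-node list) and `shapes`.
#' @export
init_model <- function(graph, seed = 0L) {
  shapes <- infer_shapes(graph)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  weights <- list()
  for (n in graph$nodes) {
    in_shape <- if (length(n$preds)) shapes[[n$preds[1]]] else NULL
    weights[[n$id]] <- switch(
      n$kind,
      conv2d = {
        k <- n$params$kernel; cin <- in_shape[3]; cout <- n$params$filters
        wts <- list(W = glorot_uniform(c(k, k, cin, cout), k * k * cin, k * k * cout))
        if (isTRUE(n$params$use_bias)) wts$b <- numeric(cout)
        wts
      },
      separable_conv2d = {
        k <- n$params$kernel; cin <- in_shape[3]; cout <- n$params$filters
        wts <- list(
          Wd = glorot_uniform(c(k, k, cin), k * k, k * k),
          Wp = glorot_uniform(c(cin, cout), cin, cout)
        )
        if (isTRUE(n$params$use_bias)) wts$b <- numeric(cout)
        wts
      },
      batch_norm = {
        ch <- in_shape[length(in_shape)]
        # running moments are zero-initialised, bias-corrected EMAs (see
        # model_node_forward); `steps` counts the updates for the correction
        list(gamma = rep(1, ch), beta = numeric(ch),
             mean = numeric(ch), var = numeric(ch), steps = 0)
      },
      dense = {
        cin <- in_shape[1]; units <- n$params$units
        list(W = glorot_uniform(c(cin, units), cin, units), b = numeric(units))
      },
      NULL
    )
  }
  structure(list(graph = graph, weights = weights, shapes = shapes),
            class = "cnn_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d nodes, %s parameters\n", length(x$graph$nodes),
              format(parameter_count(x$graph), big.mark = ",")))
  invisible(x)
}

batchnorm_stats <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) {
    m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  } else {
    m <- x
  }
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu * mu
  list(mu = mu, var = pmax(v, 0))
}

bn_broadcast <- function(vec, d) {
  # per-channel vector -> full (H,W,C,N) array layout
  rep(rep(vec, each = d[1] * d[2]), times = d[4])
}

model_node_forward <- function(node, wts, inputs, training, rng_dropout = NULL) {
  p <- node$params
  switch(
    node$kind,
    conv2d = {
      y <- .conv2d_fw(inputs[[1]], wts$W, p$stride %||% 1L,
                      (p$padding %||% "valid") == "same",
                      if (!is.null(wts$b)) wts$b else NULL)
      list(out = y)
    },
    separable_conv2d = {
      r <- .sepconv_fw(inputs[[1]], wts$Wd, wts$Wp, p$stride %||% 1L,
                       (p$padding %||% "same") == "same",
                       if (!is.null(wts$b)) wts$b else NULL)
      list(out = r$y, depthwise = r$d)
    },
    batch_norm = {
      x <- inputs[[1]]
      d <- dim(x)
      if (training) {
        st <- if (length(d) == 4L) {
          s <- .bn_stats(x); list(mu = s$mu, var = s$var)
        } else batchnorm_stats(x)
      } else if ((wts$steps %||% 0) > 0) {
        # debias the zero-initialised EMA (same correction as Adam's):
        # after t updates the EMA carries total weight 1 - momentum^t
        corr <- 1 - BN_MOMENTUM^wts$steps
        st <- list(mu = wts$mean / corr, var = wts$var / corr)
      } else {
        # never trained: fall back to the identity transform
        st <- list(mu = numeric(length(wts$gamma)),
                   var = rep(1, length(wts$gamma)))
      }
      inv_sd <- 1 / sqrt(st$var + BN_EPS)
      if (length(d) == 4L) {
        r <- .bn_fw(x, wts$gamma, wts$beta, st$mu, st$var, BN_EPS)
        xhat <- r$xhat; y <- r$y
      } else {
        xhat <- sweep(sweep(x, 2, st$mu), 2, inv_sd, "*")
        y <- sweep(sweep(xhat, 2, wts$gamma, "*"), 2, wts$beta, "+")
      }
      list(out = y, xhat = xhat, inv_sd = inv_sd, batch_mu = st$mu,
           batch_var = st$var)
    },
    relu_activation = list(out = pmax(inputs[[1]], 0)),
    max_pool = {
      r <- .maxpool_fw(inputs[[1]], p$window, p$stride %||% 1L,
                       (p$padding %||% "valid") == "same")
      list(out = r$y, idx = r$idx, in_dim = dim(inputs[[1]]))
    },
    avg_topk_pool = {
      r <- .avgtopk_fw(inputs[[1]], p$window, p$stride %||% 1L, p$K,
                       (p$padding %||% "valid") == "same")
      list(out = r$y, sel = r$sel, in_dim = dim(inputs[[1]]))
    },
    global_avg_pool = {
      x <- inputs[[1]]
      d <- dim(x)
      m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      grp <- rep(seq_len(d[4]), each = d[1] * d[2])
      y <- rowsum(m, rep(seq_len(d[4]), each = d[1] * d[2])) / (d[1] * d[2])
      dimnames(y) <- NULL
      list(out = y, in_dim = d)
    },
    flatten = {
      x <- inputs[[1]]
      d <- dim(x)
      list(out = t(matrix(x, nrow = prod(d[-length(d)]), ncol = d[length(d)])),
           in_dim = d)
    },
    add_merge = {
      y <- inputs[[1]]
      for (i in seq_along(inputs)[-1]) y <- y + inputs[[i]]
      list(out = y)
    },
    dense = list(out = sweep(inputs[[1]] %*% wts$W, 2, wts$b, "+")),
    softmax = {
      z <- inputs[[1]]
      z <- z - apply(z, 1, max)
      e <- exp(z)
      list(out = e / rowSums(e))
    },
    dropout = {
      x <- inputs[[1]]
      if (training && p$rate > 0) {
        mask <- array(runif(length(x)) >= p$rate, dim = dim(x))
        list(out = x * mask / (1 - p$rate), mask = mask)
      } else {
        list(out = x)
      }
    },
    stop(sprintf("forward: unhandled kind '%s'", node$kind))
  )
}

#' Run a forward pass
#'
#' @param model A [init_model()] object.
#' @param x Input batch, array `(H, W, C, N)` (a single image `(H, W, C)` is
#'   promoted to a batch of one).
#' @param training Logical; batch norm uses batch statistics and dropout is
#'   active when `TRUE`.
#' @param keep_all Keep every node's output (needed for profiling/backward)?
#'   If `FALSE`, only the graph output is returned.
#' @return List with `out` (output-node activation) and, when `keep_all`,
#'   `cache` (per-node forward records, each with an `out` field).
#' @export
model_forward <- function(model, x, training = FALSE, keep_all = FALSE) {
  graph <- model$graph
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  in_shape <- model$shapes[[input_id(graph)]]
  if (!identical(dim(x)[1:3], as.integer(in_shape))) {
    stop(sprintf("input batch shape [%s] does not match graph input [%s]",
                 paste(dim(x)[1:3], collapse = "x"),
                 paste(in_shape, collapse = "x")))
  }
  cache <- list()
  need <- ancestors(graph, graph$output_id)
  succ <- successor_map(graph)
  remaining <- table(unlist(lapply(graph$nodes[need], function(n) n$preds)))
  for (id in need) {
    node <- graph$nodes[[id]]
    if (node$kind == "input") {
      cache[[id]] <- list(out = x)
    } else {
      inputs <- lapply(node$preds, function(p) cache[[p]]$out)
      cache[[id]] <- model_node_forward(node, model$weights[[id]], inputs,
                                        training)
    }
    if (!keep_all) {
      # free predecessors whose consumers have all run
      for (p in node$preds) {
        remaining[[p]] <- remaining[[p]] - 1L
        if (remaining[[p]] == 0L && p != graph$output_id) cache[[p]] <- list(out = NULL)
      }
    }
  }
  out <- cache[[graph$output_id]]$out
  if (keep_all) list(out = out, cache = cache) else list(out = out)
}

# Reverse-mode gradients for softmax + sparse categorical cross-entropy.
# labels: integer vector in 1..n_classes.  Returns list(loss, grads) where
# grads mirrors model$weights, plus bn_updates (running-moment refresh).
model_backward <- function(model, cache, labels) {
  graph <- model$graph
  out_node <- graph$nodes[[graph$output_id]]
  if (out_node$kind != "softmax") stop("training requires a softmax output node")
  probs <- cache[[graph$output_id]]$out
  n <- nrow(probs)
  eps <- 1e-12
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), labels)], eps)))
  onehot <- matrix(0, n, ncol(probs))
  onehot[cbind(seq_len(n), labels)] <- 1
  dlogits <- (probs - onehot) / n

  need <- ancestors(graph, graph$output_id)
  grads <- list()
  dout <- setNames(vector("list", length(need)), need)
  # seed at the softmax *input* (fused softmax/CE gradient)
  dout[[out_node$preds[1]]] <- dlogits
  bn_updates <- list()

  for (id in rev(need)) {
    node <- graph$nodes[[id]]
    if (id == graph$output_id || node$kind == "input") next
    dy <- dout[[id]]
    if (is.null(dy)) next
    wts <- model$weights[[id]]
    c_ <- cache[[id]]
    p <- node$params
    push <- function(pred, g) {
      dout[[pred]] <<- if (is.null(dout[[pred]])) g else dout[[pred]] + g
    }
    switch(
      node$kind,
      conv2d = {
        r <- .conv2d_bw(cache[[node$preds[1]]]$out, wts$W, dy,
                        p$stride %||% 1L, (p$padding %||% "valid") == "same",
                        !is.null(wts$b))
        grads[[id]] <- list(W = r$dw)
        if (!is.null(wts$b)) grads[[id]]$b <- r$db
        push(node$preds[1], r$dx)
      },
      separable_conv2d = {
        r <- .sepconv_bw(cache[[node$preds[1]]]$out, wts$Wd, wts$Wp,
                         c_$depthwise, dy, p$stride %||% 1L,
                         (p$padding %||% "same") == "same", !is.null(wts$b))
        grads[[id]] <- list(Wd = r$dwd, Wp = r$dwp)
        if (!is.null(wts$b)) grads[[id]]$b <- r$db
        push(node$preds[1], r$dx)
      },
      batch_norm = {
        xhat <- c_$xhat
        d <- dim(xhat)
        if (length(d) == 4L) {
          r <- .bn_bw(xhat, dy, model$weights[[id]]$gamma, c_$inv_sd)
          dgamma <- r$dgamma; dbeta <- r$dbeta; dx <- r$dx
        } else {
          dgamma <- colSums(dy * xhat)
          dbeta <- colSums(dy)
          msz <- nrow(dy)
          dxhat <- sweep(dy, 2, model$weights[[id]]$gamma, "*")
          dx <- sweep(
            dxhat - matrix(colSums(dxhat) / msz, msz, ncol(dy), byrow = TRUE) -
              sweep(xhat, 2, colSums(dxhat * xhat) / msz, "*"),
            2, c_$inv_sd, "*")
        }
        grads[[id]] <- list(gamma = dgamma, beta = dbeta)
        bn_updates[[id]] <- list(mean = c_$batch_mu, var = c_$batch_var)
        push(node$preds[1], dx)
      },
      relu_activation = {
        push(node$preds[1], dy * (c_$out > 0))
      },
      max_pool = {
        push(node$preds[1], .maxpool_bw(dy, c_$idx, c_$in_dim))
      },
      avg_topk_pool = {
        push(node$preds[1], .avgtopk_bw(dy, c_$sel, c_$in_dim))
      },
      global_avg_pool = {
        d <- c_$in_dim
        dx <- array(rep(as.vector(t(dy)) / (d[1] * d[2]), each = d[1] * d[2]),
                    dim = d)
        push(node$preds[1], dx)
      },
      flatten = {
        d <- c_$in_dim
        push(node$preds[1], array(t(dy), dim = d))
      },
      add_merge = {
        for (pr in node$preds) push(pr, dy)
      },
      dense = {
        x_in <- cache[[node$preds[1]]]$out
        grads[[id]] <- list(W = crossprod(x_in, dy), b = colSums(dy))
        push(node$preds[1], dy %*% t(wts$W))
      },
      dropout = {
        if (!is.null(c_$mask)) {
          push(node$preds[1], dy * c_$mask / (1 - p$rate))
        } else {
          push(node$preds[1], dy)
        }
      },
      stop(sprintf("backward: unhandled kind '%s'", node$kind))
    )
  }
  list(loss = loss, grads = grads, bn_updates = bn_updates)
}

adam_init <- function(weights) {
  trainable <- function(id, nm) !(nm %in% c("mean", "var", "steps"))
  st <- list()
  for (id in names(weights)) {
    if (is.null(weights[[id]])) next
    for (nm in names(weights[[id]])) {
      if (!trainable(id, nm)) next
      key <- paste0(id, "/", nm)
      st[[key]] <- list(m = weights[[id]][[nm]] * 0, v = weights[[id]][[nm]] * 0)
    }
  }
  st
}

adam_step <- function(model, grads, bn_updates, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      key <- paste0(id, "/", nm)
      g <- grads[[id]][[nm]]
      s <- state[[key]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      state[[key]] <- s
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      model$weights[[id]][[nm]] <- model$weights[[id]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  for (id in names(bn_updates)) {
    model$weights[[id]]$mean <- BN_MOMENTUM * model$weights[[id]]$mean +
      (1 - BN_MOMENTUM) * bn_updates[[id]]$mean
    model$weights[[id]]$var <- BN_MOMENTUM * model$weights[[id]]$var +
      (1 - BN_MOMENTUM) * bn_updates[[id]]$var
    model$weights[[id]]$steps <- (model$weights[[id]]$steps %||% 0) + 1
  }
  list(model = model, state = state)
}
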