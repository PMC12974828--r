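#' Imbalance-handling strategy
#'
#' The four oversampling strategies: `"minority"` raises only the single
#' smallest class to the largest class's count; `"not_minority"` raises
#' every class except the smallest; `"not_majority"` raises every class
#' except the largest; `"multiplier"` multiplies every non-largest class's
#' count by `k`, capped at the largest count.
#'
#' @param mode One of `"minority"`, `"not_minority"`, `"not_majority"`,
#'   `"multiplier"`.
#' @param k Multiplication factor (positive integer; multiplier mode only).
#' @return An object of class `imbalance_strategy`.
#' @export
imbalance_strategy <- function(mode, k = NULL) {
  mode <- match.arg(mode, c("minority", "not_minority", "not_majority",
                            "multiplier"))
  if (mode == "multiplier") {
    if (is.null(k) || k < 1 || k != round(k)) {
      stop("multiplier mode requires integer k >= 1")
    }
    k <- as.integer(k)
  } else if (!is.null(k)) {
    stop("k is only meaningful for multiplier mode")
  }
  structure(list(mode = mode, k = k), class = "imbalance_strategy")
}

#' SMOTE configuration
#'
#' @param k_neighbors Number of nearest neighbours considered per sample
#'   (default 5, the canonical SMOTE setting); clamped to class size - 1
#'   with a warning when a class is smaller.
#' @param seed Integer seed for base-sample order, neighbour choice and the
#'   interpolation draws.
#' @param space `"pixel"` (interpolate raw images channel-wise) or
#'   `"feature"` (interpolate extracted feature vectors).
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, seed = 1L, space = "pixel") {
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  space <- match.arg(space, c("pixel", "feature"))
  structure(list(k_neighbors = k_neighbors, seed = as.integer(seed),
                 space = space),
            class = "smote_config")
}

#' Target class counts under a sampling strategy
#'
#' Exact target-count arithmetic for each strategy (see
#' [imbalance_strategy()]).  For `multiplier`, each non-largest class is set
#' to `min(k * count, largest count)` and the largest class is unchanged.
#'
#' @param counts Non-negative integer vector of per-class counts (at least
#'   two classes).
#' @param strategy An [imbalance_strategy()].
#' @param tie_break Optional class index resolving ties for the smallest /
#'   largest class; without it, ties raise an error.
#' @return Integer vector of target counts (same names/order as `counts`).
#' @export
target_counts <- function(counts, strategy, tie_break = NULL) {
  stopifnot(inherits(strategy, "imbalance_strategy"))
  counts <- setNames(as.integer(counts), names(counts))
  if (length(counts) < 2L) stop("need at least two classes")
  if (any(counts < 0L)) stop("counts must be non-negative")
  maxc <- max(counts)
  minc <- min(counts)
  pick_unique <- function(which_val, what) {
    idx <- which(counts == which_val)
    if (length(idx) > 1L) {
      if (is.null(tie_break)) {
        stop(sprintf("tie for the %s class (classes %s); supply tie_break",
                     what, paste(idx, collapse = ", ")))
      }
      if (!tie_break %in% idx) stop("tie_break does not name a tied class")
      idx <- tie_break
    }
    idx
  }
  out <- counts
  switch(
    strategy$mode,
    minority = {
      i <- pick_unique(minc, "smallest")
      out[i] <- maxc
    },
    not_minority = {
      i <- pick_unique(minc, "smallest")
      out[-i] <- maxc
    },
    not_majority = {
      i <- pick_unique(maxc, "largest")
      out[-i] <- maxc
    },
    multiplier = {
      i <- pick_unique(maxc, "largest")
      grow <- setdiff(seq_along(counts), i)
      out[grow] <- pmin(strategy$k * counts[grow], maxc)
    }
  )
  out
}

#' SMOTE interpolation between two samples
#'
#' The convex combination `x_new = x_i + lambda * (x_nn - x_i)`, applied
#' elementwise (per pixel, per channel for images).
#'
#' @param x_i,x_nn Numeric arrays/vectors of identical shape.
#' @param lambda Scalar in `[0, 1]`.
#' @return The interpolated sample (real-valued; integer inputs are
#'   promoted).
#' @export
smote_interpolate <- function(x_i, x_nn, lambda) {
  if (!identical(dim(x_i) %||% length(x_i), dim(x_nn) %||% length(x_nn))) {
    stop("x_i and x_nn have different shapes")
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  x_i + lambda * (as.numeric(x_nn) - as.numeric(x_i))
}

#' Within-class nearest neighbours
#'
#' Euclidean distances on flattened features; for each sample the `k`
#' nearest same-class samples, self excluded, distance ties broken by
#' ascending index.
#'
#' @param class_samples Matrix `(n, F)` of flattened features (one row per
#'   sample; an `(H, W, C, n)` array is flattened automatically).
#' @param k Number of neighbours; clamped to `n - 1` with a warning.
#' @return List of length n of integer index vectors.
#' @export
nearest_neighbors <- function(class_samples, k) {
  if (!is.matrix(class_samples)) {
    d <- dim(class_samples)
    class_samples <- t(matrix(class_samples, nrow = prod(d[-length(d)])))
  }
  n <- nrow(class_samples)
  if (n < 2L) stop("need at least 2 samples to find neighbours")
  if (k >= n) {
    warning(sprintf("k = %d >= class size %d; clamped to %d", k, n, n - 1L))
    k <- n - 1L
  }
  dmat <- as.matrix(stats::dist(class_samples))
  lapply(seq_len(n), function(i) {
    di <- dmat[i, -i]
    others <- seq_len(n)[-i]
    others[order(di, others)][seq_len(k)]
  })
}

#' Resample a training set with SMOTE
#'
#' For every class whose [target_counts()] exceed its current count,
#' synthetic samples are generated by interpolating between a base sample
#' (round-robin over a seeded shuffle of the class) and one of its k nearest
#' same-class neighbours chosen uniformly, with `lambda ~ Uniform(0, 1)`.
#' Original items are preserved bitwise; synthetic items carry provenance
#' `"synthetic"`.  Apply only to the training split, never to validation or
#' test data.
#'
#' @param dataset A [labeled_image_set()] (pixel- or feature-space, matching
#'   `config$space`).
#' @param strategy An [imbalance_strategy()].
#' @param config A [smote_config()].
#' @param tie_break Passed to [target_counts()].
#' @return A [labeled_image_set()] whose per-class counts equal the targets
#'   exactly.
#' @export
resample <- function(dataset, strategy, config = smote_config(),
                     tie_break = NULL) {
  stopifnot(inherits(dataset, "labeled_image_set"),
            inherits(config, "smote_config"))
  if (config$space == "feature" && !is_feature_space(dataset)) {
    stop("space='feature' requires a feature-space set (see extract_features)")
  }
  counts <- class_counts(dataset)
  targets <- target_counts(counts, strategy, tie_break)
  deficits <- targets - counts
  if (all(deficits == 0L)) return(dataset)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  feature <- is_feature_space(dataset)
  get_item <- function(i) {
    if (feature) dataset$images[i, ] else dataset$images[, , , i]
  }
  synth_list <- list()
  synth_labels <- integer(0)
  for (cls in seq_along(counts)) {
    need <- deficits[cls]
    if (need <= 0L) next
    idx <- which(dataset$labels == cls)
    if (length(idx) < 2L) {
      stop(sprintf("class '%s' has %d sample(s); SMOTE needs at least 2",
                   dataset$class_names[cls], length(idx)))
    }
    feats <- t(vapply(idx, function(i) as.numeric(get_item(i)),
                      numeric(length(get_item(idx[1])))))
    k <- config$k_neighbors
    nn <- if (k >= length(idx)) {
      suppressWarnings(nearest_neighbors(feats, k))
    } else {
      nearest_neighbors(feats, k)
    }
    base_order <- sample(length(idx))
    for (j in seq_len(need)) {
      b <- base_order[((j - 1L) %% length(idx)) + 1L]
      nbr <- nn[[b]][sample.int(length(nn[[b]]), 1L)]
      lambda <- runif(1)
      synth_list[[length(synth_list) + 1L]] <-
        smote_interpolate(feats[b, ], feats[nbr, ], lambda)
      synth_labels <- c(synth_labels, cls)
    }
  }
  n_new <- length(synth_list)
  if (feature) {
    new_imgs <- do.call(rbind, synth_list)
  } else {
    d <- dim(dataset$images)
    new_imgs <- array(unlist(synth_list), dim = c(d[1:3], n_new))
  }
  synth <- labeled_image_set(new_imgs, synth_labels, dataset$class_names,
                             rep("synthetic", n_new))
  bind_items(dataset, synth)
}

#' Extract deep features for feature-space resampling
#'
#' Runs images through a (typically pruned) backbone and global-average
#' pools the output, yielding one feature vector per image; SMOTE can then
#' interpolate in this space instead of the raw pixel space.
#'
#' @param model A `cnn_model` whose output is spatial or already pooled.
#' @param dataset A pixel-space [labeled_image_set()].
#' @param rescale Divide pixels by 255 first (default `TRUE`).
#' @param batch_size Forward-pass batch size.
#' @return A feature-space [labeled_image_set()] (matrix `(N, F)`).
#' @export
extract_features <- function(model, dataset, rescale = TRUE, batch_size = 32L) {
  n <- n_items(dataset)
  out_shape <- model$shapes[[model$graph$output_id]]
  feats <- NULL
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + batch_size - 1L, n)
    x <- dataset$images[, , , idx, drop = FALSE]
    if (rescale) x <- x / 255
    y <- model_forward(model, x)$out
    if (length(dim(y)) == 4L) {
      d <- dim(y)
      y <- rowsum(matrix(aperm(y, c(1, 2, 4, 3)), ncol = d[3]),
                  rep(seq_len(d[4]), each = d[1] * d[2])) / (d[1] * d[2])
      dimnames(y) <- NULL
    }
    if (is.null(feats)) feats <- matrix(0, n, ncol(y))
    feats[idx, ] <- y
    at <- at + batch_size
  }
  labeled_image_set(feats, dataset$labels, dataset$class_names,
                    dataset$provenance)
}
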