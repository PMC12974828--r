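#' Augmentation configuration
#'
#' The stochastic photometric/geometric recipe applied to training images:
#' rescale to `[0, 1]`, rotate by up to `rotation_max_deg` degrees, shift
#' width/height by up to the given fractions, shear, and flip horizontally
#' and/or vertically; pixels falling outside the frame are filled by
#' nearest-neighbour (edge-clamped) sampling.
#'
#' @param rescale Pixel scaling factor (default `1/255`).
#' @param rotation_max_deg Maximum absolute rotation in degrees (default 10).
#' @param width_shift_frac,height_shift_frac Maximum absolute shift as a
#'   fraction of the image side (default 0.2 each).
#' @param shear_range Maximum absolute shear coefficient (default 0.2).
#' @param horizontal_flip,vertical_flip Enable the respective random flips
#'   (default `TRUE`).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rescale = 1 / 255, rotation_max_deg = 10,
                           width_shift_frac = 0.2, height_shift_frac = 0.2,
                           shear_range = 0.2, horizontal_flip = TRUE,
                           vertical_flip = TRUE) {
  if (rotation_max_deg < 0) stop("rotation_max_deg must be >= 0")
  for (f in c(width_shift_frac, height_shift_frac)) {
    if (f < 0 || f > 1) stop("shift fractions must be in [0, 1]")
  }
  structure(list(rescale = rescale, rotation_max_deg = rotation_max_deg,
                 width_shift_frac = width_shift_frac,
                 height_shift_frac = height_shift_frac,
                 shear_range = shear_range,
                 horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip)),
            class = "augment_config")
}

#' Randomly augment one image
#'
#' Draws a transformation from the config (rotation, shifts, shear, flips)
#' and applies it with nearest-neighbour sampling; coordinates falling
#' outside the source frame are clamped to the nearest edge pixel.  The
#' output is rescaled, so values lie in `[0, 1]` for 0-255 input.
#'
#' @param image Array `(H, W, 3)` of pixel values.
#' @param config An [augment_config()].
#' @param draw Optional explicit parameter list
#'   `list(angle, shift_x, shift_y, shear, hflip, vflip)` overriding the
#'   random draw (used for deterministic checks; `NULL` values are drawn).
#' @return Augmented image `(H, W, 3)` in rescaled units.
#' @export
sample_augmentation <- function(image, config = augment_config(), draw = NULL) {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be (H, W, C)")
  H <- d[1]; W <- d[2]
  g <- list(
    angle = runif(1, -config$rotation_max_deg, config$rotation_max_deg),
    shift_x = runif(1, -config$width_shift_frac, config$width_shift_frac) * W,
    shift_y = runif(1, -config$height_shift_frac, config$height_shift_frac) * H,
    shear = runif(1, -config$shear_range, config$shear_range),
    hflip = config$horizontal_flip && runif(1) < 0.5,
    vflip = config$vertical_flip && runif(1) < 0.5
  )
  if (!is.null(draw)) g <- modifyList(g, draw)
  out <- image * config$rescale
  identity_geom <- g$angle == 0 && g$shift_x == 0 && g$shift_y == 0 &&
    g$shear == 0
  if (!identity_geom || g$hflip || g$vflip) {
    th <- g$angle * pi / 180
    # forward map: rotate then shear then shift (about the image centre);
    # invert it to pull source coordinates for each output pixel
    Mf <- matrix(c(cos(th), sin(th), -sin(th) + g$shear * cos(th),
                   cos(th) + g$shear * sin(th)), 2, 2)
    A <- solve(Mf)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    ys <- matrix(rep(seq_len(H), times = W), H, W) - cy
    xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
    if (g$hflip) xs <- -xs
    if (g$vflip) ys <- -ys
    px <- xs - g$shift_x
    py <- ys - g$shift_y
    sx <- A[1, 1] * px + A[1, 2] * py + cx
    sy <- A[2, 1] * px + A[2, 2] * py + cy
    i <- pmin(pmax(round(sy), 1L), H)
    j <- pmin(pmax(round(sx), 1L), W)
    flat <- cbind(as.vector(i), as.vector(j))
    res <- out
    for (ch in seq_len(d[3])) {
      plane <- out[, , ch]
      res[, , ch] <- matrix(plane[flat], H, W)
    }
    out <- res
  }
  out
}

#' Equalize class counts with augmented copies
#'
#' Fills each class's deficit up to `targets` with augmented copies of
#' randomly chosen members of the same class (provenance `"augmented"`).
#' Augmented copies are stored back on the dataset's 0-255 pixel scale so
#' the set stays homogeneous.
#'
#' @param train_set A pixel-space [labeled_image_set()].
#' @param targets Integer vector of per-class targets, `>=` current counts.
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @return A [labeled_image_set()] whose class counts equal `targets`.
#' @export
balance_with_augmentation <- function(train_set, targets,
                                      config = augment_config(), seed = 1L) {
  counts <- class_counts(train_set)
  targets <- as.integer(targets)
  if (length(targets) != length(counts)) stop("targets length must match classes")
  if (any(targets < counts)) stop("targets must be >= current counts")
  deficits <- targets - counts
  if (all(deficits == 0L)) return(train_set)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- dim(train_set$images)
  n_new <- sum(deficits)
  new_imgs <- array(0, dim = c(d[1:3], n_new))
  new_labels <- integer(n_new)
  at <- 0L
  for (cls in seq_along(counts)) {
    need <- deficits[cls]
    if (need <= 0L) next
    idx <- which(train_set$labels == cls)
    if (length(idx) == 0L) {
      stop(sprintf("class '%s' is empty but has target %d",
                   train_set$class_names[cls], targets[cls]))
    }
    parents <- idx[sample.int(length(idx), need, replace = TRUE)]
    for (p in parents) {
      at <- at + 1L
      aug <- sample_augmentation(train_set$images[, , , p], config)
      new_imgs[, , , at] <- pmin(pmax(aug / config$rescale, 0), 255)
      new_labels[at] <- cls
    }
  }
  aug_set <- labeled_image_set(new_imgs, new_labels, train_set$class_names,
                               rep("augmented", n_new))
  bind_items(train_set, aug_set)
}
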