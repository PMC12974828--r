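HAM10000_CLASSES <- c("nv", "mel", "bkl", "bcc", "akiec", "vasc", "df")
HAM10000_COUNTS <- c(nv = 6705L, mel = 1113L, bkl = 1099L, bcc = 514L,
                     akiec = 327L, vasc = 142L, df = 115L)

# Class-conditional appearance parameters: lesion colour (RGB, 0-255),
# ellipse eccentricity, border roughness amplitude, border lobe count and
# internal texture frequency.  Chosen so the seven classes differ in hue,
# shape and texture, like (but far simpler than) dermoscopic lesion types.
SYNTH_CLASS_PARAMS <- data.frame(
  class = HAM10000_CLASSES,
  r = c(135, 60, 160, 170, 180, 150, 110),
  g = c(90, 40, 120, 110, 90, 60, 85),
  b = c(70, 45, 90, 110, 80, 90, 75),
  ecc = c(0.25, 0.45, 0.30, 0.35, 0.50, 0.20, 0.30),
  rough = c(0.05, 0.25, 0.15, 0.10, 0.20, 0.05, 0.10),
  lobes = c(3, 7, 5, 4, 8, 2, 6),
  texfreq = c(2, 6, 10, 4, 14, 1, 8),
  stringsAsFactors = FALSE
)

#' Synthetic-dataset specification
#'
#' Describes a seeded synthetic dermoscopy-like dataset: a skin-toned
#' background with one elliptical lesion per image whose hue, eccentricity,
#' border roughness and internal texture frequency are drawn from
#' class-specific distributions.  The default class counts reproduce the
#' HAM10000 seven-class distribution (nv/mel/bkl/bcc/akiec/vasc/df =
#' 6705/1113/1099/514/327/142/115, 10,015 images in total).
#'
#' @param class_counts Named integer vector of per-class image counts
#'   (default the HAM10000 distribution).
#' @param image_size Image side in pixels (>= 16; default 64 for desk-scale
#'   work, 128 matching full-resolution practice).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param difficulty Separation scale in (0, 1]: 1 keeps the class
#'   appearance parameters fully separated, smaller values shrink them
#'   toward a common mean, making classes harder to tell apart.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_counts = HAM10000_COUNTS, image_size = 64L,
                           seed = 1L, difficulty = 1.0) {
  if (is.null(names(class_counts))) {
    names(class_counts) <- HAM10000_CLASSES[seq_along(class_counts)]
  }
  class_counts <- setNames(as.integer(class_counts), names(class_counts))
  if (any(class_counts < 0L)) stop("class counts must be >= 0")
  image_size <- as.integer(image_size)
  if (image_size < 16L) stop("image_size must be >= 16")
  if (difficulty <= 0 || difficulty > 1) stop("difficulty must be in (0, 1]")
  structure(list(class_counts = class_counts, image_size = image_size,
                 seed = as.integer(seed), difficulty = difficulty),
            class = "synthetic_spec")
}

synth_class_params <- function(k, difficulty, class_name = NULL) {
  # look the recipe up by class name when it is one of the known classes, so
  # e.g. a two-class (nv, vasc) spec uses the vasc recipe, not the second row
  row <- if (!is.null(class_name) && class_name %in% SYNTH_CLASS_PARAMS$class) {
    match(class_name, SYNTH_CLASS_PARAMS$class)
  } else {
    ((k - 1L) %% nrow(SYNTH_CLASS_PARAMS)) + 1L
  }
  p <- SYNTH_CLASS_PARAMS[row, ]
  num <- c("r", "g", "b", "ecc", "rough", "lobes", "texfreq")
  means <- colMeans(SYNTH_CLASS_PARAMS[num])
  for (f in num) p[[f]] <- means[[f]] + difficulty * (p[[f]] - means[[f]])
  p
}

synth_one_image <- function(size, p, xx, yy) {
  # background: skin tone with slight per-image cast
  bg <- c(214, 172, 150) + rnorm(3, 0, 6)
  # lesion geometry
  cx <- runif(1, 0.38, 0.62) * size
  cy <- runif(1, 0.38, 0.62) * size
  r0 <- runif(1, 0.18, 0.30) * size
  ecc <- max(min(p$ecc + rnorm(1, 0, 0.05), 0.9), 0)
  theta <- runif(1, 0, pi)
  rough <- max(p$rough + rnorm(1, 0, 0.02), 0)
  lobes <- max(1, round(p$lobes + sample(-1:1, 1)))
  phase <- runif(1, 0, 2 * pi)
  dx <- xx - cx
  dy <- yy - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  a <- r0
  b <- r0 * (1 - ecc)
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  phi <- atan2(yr / b, xr / a)
  edge <- 1 + rough * sin(lobes * phi + phase)
  # soft membership in [0,1]; ~2px transition band
  inside <- 1 / (1 + exp((rho - edge) * (size / 6)))
  # internal texture: oriented sinusoid modulating lesion brightness
  texdir <- runif(1, 0, pi)
  tex <- 1 + 0.15 * sin(2 * pi * p$texfreq *
                          (xx * cos(texdir) + yy * sin(texdir)) / size)
  col <- c(p$r, p$g, p$b) + rnorm(3, 0, 8)
  img <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) {
    lesion <- col[ch] * tex
    img[, , ch] <- bg[ch] * (1 - inside) + lesion * inside
  }
  img <- img + array(rnorm(length(img), 0, 5), dim = dim(img))
  pmin(pmax(round(img), 0), 255)
}

#' Generate a synthetic labeled image set
#'
#' Images are generated class by class in `class_counts` order, fully
#' deterministically for a given spec (same seed, bitwise-identical stacks).
#'
#' @param spec A [synthetic_spec()].
#' @return A [labeled_image_set()] with 8-bit pixel values in `[0, 255]`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  size <- spec$image_size
  n <- sum(spec$class_counts)
  xx <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  yy <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  imgs <- array(0, dim = c(size, size, 3L, n))
  labels <- integer(n)
  at <- 0L
  for (k in seq_along(spec$class_counts)) {
    p <- synth_class_params(k, spec$difficulty,
                            names(spec$class_counts)[k])
    for (i in seq_len(spec$class_counts[k])) {
      at <- at + 1L
      imgs[, , , at] <- synth_one_image(size, p, xx, yy)
      labels[at] <- k
    }
  }
  labeled_image_set(imgs, labels, names(spec$class_counts))
}
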