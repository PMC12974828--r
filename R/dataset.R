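#' Labeled image set
#'
#' The unit of data flowing through resampling, augmentation and training:
#' a stack of RGB images with integer class labels, a class-name table, and
#' a per-item provenance flag (`"original"`, `"synthetic"` for SMOTE output,
#' `"augmented"` for augmentation copies).
#'
#' @param images Array `(H, W, C, N)` of pixel values (0..255 scale for raw
#'   images) or a feature matrix `(N, F)` for feature-space sets.
#' @param labels Integer vector of length N with values in
#'   `1..length(class_names)`.
#' @param class_names Ordered character vector of class names.
#' @param provenance Character vector of length N (default all
#'   `"original"`).
#' @return An object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, class_names,
                              provenance = rep("original", length(labels))) {
  labels <- as.integer(labels)
  if (is.matrix(images)) {
    n <- nrow(images)
  } else {
    d <- dim(images)
    if (length(d) != 4L) stop("images must be an (H, W, C, N) array or an (N, F) matrix")
    n <- d[4]
  }
  if (length(labels) != n) stop("labels length does not match image count")
  if (length(provenance) != n) stop("provenance length does not match image count")
  if (n > 0L && (min(labels) < 1L || max(labels) > length(class_names))) {
    stop("labels out of range of class_names")
  }
  bad <- setdiff(unique(provenance), c("original", "synthetic", "augmented"))
  if (length(bad)) stop("unknown provenance: ", paste(bad, collapse = ", "))
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 provenance = as.character(provenance)),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("<labeled_image_set> %d items, %d classes\n",
              n_items(x), length(x$class_names)))
  print(manifest(x))
  invisible(x)
}

#' Number of items in a labeled set
#'
#' @param dataset A [labeled_image_set()].
#' @return Integer item count.
#' @export
n_items <- function(dataset) length(dataset$labels)

#' Is a labeled set feature-space?
#'
#' @param dataset A [labeled_image_set()].
#' @return `TRUE` for feature-matrix sets (see [extract_features()]),
#'   `FALSE` for pixel-space image stacks.
#' @export
is_feature_space <- function(dataset) is.matrix(dataset$images)

#' Number of items per class
#'
#' @param dataset A [labeled_image_set()].
#' @return Named integer vector over all classes (zeros included), in
#'   `class_names` order.
#' @export
class_counts <- function(dataset) {
  cnt <- tabulate(dataset$labels, nbins = length(dataset$class_names))
  setNames(as.integer(cnt), dataset$class_names)
}

#' Subset a labeled image set
#'
#' @param dataset A [labeled_image_set()].
#' @param idx Integer indices of items to keep.
#' @return A [labeled_image_set()] with the selected items.
#' @export
subset_items <- function(dataset, idx) {
  idx <- as.integer(idx)
  imgs <- if (is_feature_space(dataset)) {
    dataset$images[idx, , drop = FALSE]
  } else {
    dataset$images[, , , idx, drop = FALSE]
  }
  labeled_image_set(imgs, dataset$labels[idx], dataset$class_names,
                    dataset$provenance[idx])
}

#' Concatenate labeled image sets
#'
#' @param ... Sets sharing class_names and image shape.
#' @return A single [labeled_image_set()].
#' @export
bind_items <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, Negate(is.null), logical(1))]
  stopifnot(length(sets) >= 1L)
  cn <- sets[[1]]$class_names
  for (s in sets) {
    if (!identical(s$class_names, cn)) stop("class_names differ across sets")
  }
  if (is_feature_space(sets[[1]])) {
    imgs <- do.call(rbind, lapply(sets, function(s) s$images))
  } else {
    d <- dim(sets[[1]]$images)
    total <- sum(vapply(sets, n_items, integer(1)))
    imgs <- array(0, dim = c(d[1:3], total))
    at <- 0L
    for (s in sets) {
      ni <- n_items(s)
      if (ni > 0L) imgs[, , , at + seq_len(ni)] <- s$images
      at <- at + ni
    }
  }
  labeled_image_set(imgs,
                    unlist(lapply(sets, function(s) s$labels)),
                    cn,
                    unlist(lapply(sets, function(s) s$provenance)))
}

#' Per-class manifest of a dataset
#'
#' @param dataset A [labeled_image_set()].
#' @return A data.frame with one row per class: `class_name`, total `n`, and
#'   counts by provenance (`n_original`, `n_synthetic`, `n_augmented`).
#' @export
manifest <- function(dataset) {
  k <- length(dataset$class_names)
  tab <- function(keep) tabulate(dataset$labels[keep], nbins = k)
  data.frame(
    class_name = dataset$class_names,
    n = as.integer(tabulate(dataset$labels, nbins = k)),
    n_original = as.integer(tab(dataset$provenance == "original")),
    n_synthetic = as.integer(tab(dataset$provenance == "synthetic")),
    n_augmented = as.integer(tab(dataset$provenance == "augmented")),
    stringsAsFactors = FALSE
  )
}

#' Write a labeled image set to a directory
#'
#' Writes one PNG per item under per-class subdirectories plus a
#' `manifest.csv` (`image_id`, `label`, `provenance`); the layout mirrors
#' common dermoscopy-archive metadata and round-trips losslessly through
#' [read_image_directory()].
#'
#' @param dataset A pixel-space [labeled_image_set()].
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_labeled_set <- function(dataset, path) {
  if (is_feature_space(dataset)) stop("feature-space sets cannot be written as images")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- character(n_items(dataset))
  for (i in seq_len(n_items(dataset))) {
    cls <- dataset$class_names[dataset$labels[i]]
    dir.create(file.path(path, cls), showWarnings = FALSE)
    ids[i] <- sprintf("%s_%06d", cls, i)
    img <- dataset$images[, , , i] / 255
    png::writePNG(pmin(pmax(img, 0), 1), file.path(path, cls, paste0(ids[i], ".png")))
  }
  man <- data.frame(image_id = ids,
                    label = dataset$class_names[dataset$labels],
                    provenance = dataset$provenance,
                    stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a labeled image set from a directory
#'
#' Expects the layout written by [write_labeled_set()]: per-class PNG
#' subdirectories and an optional `manifest.csv`.  Without a manifest the
#' subdirectory names define the classes.
#'
#' @param path Directory path.
#' @param class_names Optional class ordering; defaults to the manifest's
#'   (or sorted subdirectory) order.
#' @return A [labeled_image_set()].
#' @export
read_image_directory <- function(path, class_names = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  man_path <- file.path(path, "manifest.csv")
  dirs <- list.dirs(path, recursive = FALSE, full.names = FALSE)
  if (file.exists(man_path)) {
    man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
    if (is.null(class_names)) class_names <- unique(man$label)
    bad <- setdiff(man$label, class_names)
    if (length(bad)) {
      stop("manifest labels absent from class_names: ", paste(unique(bad), collapse = ", "))
    }
    extra <- setdiff(dirs, class_names)
    if (length(extra)) {
      stop("class directories not in manifest/class_names: ", paste(extra, collapse = ", "))
    }
    files <- file.path(path, man$label, paste0(man$image_id, ".png"))
    missing <- files[!file.exists(files)]
    if (length(missing)) stop("manifest references missing files: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    labels <- match(man$label, class_names)
    prov <- if ("provenance" %in% names(man)) man$provenance else rep("original", nrow(man))
  } else {
    if (is.null(class_names)) class_names <- sort(dirs)
    files <- character(0); labels <- integer(0)
    for (cls in class_names) {
      fs <- sort(list.files(file.path(path, cls), pattern = "\\.png$",
                            full.names = TRUE))
      files <- c(files, fs)
      labels <- c(labels, rep(match(cls, class_names), length(fs)))
    }
    prov <- rep("original", length(files))
  }
  if (length(files) == 0L) {
    warning("no images found under ", path)
    return(labeled_image_set(array(0, c(1, 1, 3, 0)), integer(0), class_names))
  }
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 2L) dim(first) <- c(dim(first), 1L)
  d <- dim(first)
  imgs <- array(0, dim = c(d[1], d[2], 3L, length(files)))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
    imgs[, , , i] <- round(img[, , 1:3] * 255)
  }
  labeled_image_set(imgs, labels, class_names, prov)
}
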