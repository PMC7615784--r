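# Dataset plumbing: class-per-subdirectory image trees, stratified splits,
# and assembly of the mixed (original + synthetic) training set. Image
# decoding and resizing are delegated to EBImage.

# Read one image file as an H x W x 3 array in [0, 255], resized with
# bilinear interpolation. EBImage stores images [x, y, channel] in [0, 1].
read_image_file <- function(path, image_size) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) {
    img <- EBImage::Image(array(rep(as.vector(img), 3), c(d, 3)),
                          colormode = "Color")
  } else if (d[3] > 3L) {
    img <- img[, , 1:3]                            # drop alpha
  } else if (d[3] == 2L) {
    img <- EBImage::Image(array(as.vector(img[, , 1]), c(d[1], d[2], 3)),
                          colormode = "Color")
  }
  img <- EBImage::resize(img, w = image_size[2], h = image_size[1])
  a <- as.array(img)
  # EBImage x = column, y = row: transpose to row-major H x W x 3
  out <- aperm(array(a, c(dim(a)[1], dim(a)[2], 3)), c(2, 1, 3))
  pmin(pmax(out * 255, 0), 255)
}

#' Load a class-per-subdirectory image dataset
#'
#' Reads every PNG/JPEG/TIFF under `root_dir/<class>/`, resizing each image
#' to `image_size` with bilinear interpolation. Files are visited in
#' lexicographic path order, so two loads of the same tree yield identical
#' image and label order on any platform.
#'
#' @param root_dir Directory containing one subdirectory per class.
#' @param class_names Ordered class names; defaults to the sorted
#'   subdirectory names. Each named class directory must exist and contain
#'   at least one readable image.
#' @param image_size Target `c(H, W)`; default 224 x 224, the customary
#'   input resolution of ImageNet-style backbones.
#' @return An [image_set] with `provenance = "original"`.
#' @export
load_image_dataset <- function(root_dir, class_names = NULL,
                               image_size = c(224, 224)) {
  if (!dir.exists(root_dir)) abort(paste("no such directory:", root_dir))
  subdirs <- sort(list.dirs(root_dir, recursive = FALSE, full.names = FALSE))
  class_names <- class_names %||% subdirs
  if (length(class_names) < 2L) abort("need at least two class directories")
  images <- list()
  labels <- integer(0)
  for (k in seq_along(class_names)) {
    cls_dir <- file.path(root_dir, class_names[k])
    if (!dir.exists(cls_dir)) {
      abort(paste0("missing class directory: '", class_names[k], "'"))
    }
    files <- sort(list.files(cls_dir, full.names = TRUE,
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE))
    loaded <- list()
    for (f in files) {
      im <- tryCatch(read_image_file(f, image_size), error = function(e) {
        warn(paste("skipping unreadable image:", f))
        NULL
      })
      if (!is.null(im)) loaded[[length(loaded) + 1L]] <- im
    }
    if (length(loaded) == 0L) {
      abort(paste0("class '", class_names[k], "' has no readable images"))
    }
    images <- c(images, loaded)
    labels <- c(labels, rep(k, length(loaded)))
  }
  image_set(images, labels, class_names)
}

#' Stratified train/test split
#'
#' Splits an [image_set] per class after a seeded shuffle. Either a global
#' `train_fraction` or explicit `per_class_counts` (named or ordered list
#' with `train`/`test` counts per class) may be given; the reference
#' configuration for the public blood-cell data splits roughly 70/30
#' (e.g. 2184 training / 936 testing eosinophils).
#'
#' @param data An [image_set].
#' @param train_fraction Fraction of each class assigned to training.
#' @param per_class_counts Optional list of `c(train, test)` integer pairs,
#'   one per class, overriding `train_fraction`.
#' @param seed Integer seed for the shuffle.
#' @return `list(train = image_set, test = image_set)`.
#' @export
split_dataset <- function(data, train_fraction = 0.7,
                          per_class_counts = NULL, seed = 1) {
  stopifnot(inherits(data, "image_set"))
  if (is.null(per_class_counts)) train_fraction <-
    assert_fraction(train_fraction, "train_fraction")
  train_idx <- integer(0)
  test_idx <- integer(0)
  with_seed(seed, {
    for (k in seq_along(data$class_names)) {
      idx <- which(data$labels == k)
      if (length(idx) < 2L) {
        abort(paste0("class '", data$class_names[k],
                     "' has fewer than 2 images"))
      }
      idx <- idx[sample.int(length(idx))]
      if (!is.null(per_class_counts)) {
        cnt <- per_class_counts[[k]]
        n_tr <- as.integer(cnt[1])
        n_te <- as.integer(cnt[2])
        if (n_tr + n_te > length(idx)) {
          abort(paste0("explicit counts exceed class size for '",
                       data$class_names[k], "'"))
        }
      } else {
        n_tr <- round(train_fraction * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        n_te <- length(idx) - n_tr
      }
      train_idx <- c(train_idx, idx[seq_len(n_tr)])
      test_idx <- c(test_idx, idx[n_tr + seq_len(n_te)])
    }
  })
  list(train = subset_image_set(data, sort(train_idx)),
       test = subset_image_set(data, sort(test_idx)))
}

#' Assemble the mixed (original + synthetic) training set
#'
#' Appends GAN-generated images to a training split, the augmentation that
#' turns the original dataset into the mixed dataset. Only training splits
#' may be augmented: the evaluation contract is that test sets contain
#' original images exclusively.
#'
#' @param train Training [image_set] (originals).
#' @param synthetic An [image_set] of generated images with
#'   `provenance = "synthetic"` and the same class table.
#' @return The combined training [image_set].
#' @export
assemble_mixed_dataset <- function(train, synthetic) {
  stopifnot(inherits(train, "image_set"), inherits(synthetic, "image_set"))
  if (length(synthetic) == 0L) return(train)
  if (!identical(train$class_names, synthetic$class_names)) {
    abort("class tables of `train` and `synthetic` differ")
  }
  if (!all(synthetic$provenance == "synthetic")) {
    abort("all images in `synthetic` must carry provenance = 'synthetic'")
  }
  image_set(c(train$images, synthetic$images),
            c(train$labels, synthetic$labels),
            train$class_names,
            c(train$provenance, synthetic$provenance))
}

#' Write an image set as a class-per-subdirectory PNG tree
#'
#' @param data An [image_set].
#' @param dir Output directory (created if needed).
#' @param split Optional split tag recorded in the manifest.
#' @return Invisibly, a manifest tibble (`path`, `label`, `class`,
#'   `provenance`, `split`), also written to `dir/manifest.csv`.
#' @export
write_image_set <- function(data, dir, split = NA_character_) {
  stopifnot(inherits(data, "image_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- integer(length(data$class_names))
  paths <- character(length(data$images))
  for (i in seq_along(data$images)) {
    k <- data$labels[i]
    counts[k] <- counts[k] + 1L
    cls_dir <- file.path(dir, data$class_names[k])
    dir.create(cls_dir, showWarnings = FALSE)
    paths[i] <- file.path(cls_dir,
                          sprintf("%s_%05d.png", data$provenance[i],
                                  counts[k]))
    im <- aperm(data$images[[i]] / 255, c(2, 1, 3))  # back to EBImage x,y
    EBImage::writeImage(EBImage::Image(im, colormode = "Color"), paths[i])
  }
  manifest <- tibble(path = paths,
                     label = data$labels,
                     class = data$class_names[data$labels],
                     provenance = data$provenance,
                     split = split)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
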