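#' Labeled image set
#'
#' The container moved between augmentation, fine-tuning, and evaluation:
#' a list of H x W x 3 arrays with intensities in \[0, 255\], an integer
#' class label per image (1-based index into `class_names`), and a per-image
#' provenance tag distinguishing original photographs from GAN synthetics.
#'
#' @param images List of numeric H x W x 3 arrays with values in \[0, 255\].
#' @param labels Integer vector, one label per image, each in
#'   `1:length(class_names)`.
#' @param class_names Ordered character vector of class names.
#' @param provenance Character vector (`"original"` or `"synthetic"`),
#'   recycled if length 1.
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, labels, class_names,
                      provenance = "original") {
  if (!is.list(images)) abort("`images` must be a list of arrays")
  labels <- as.integer(labels)
  if (length(images) != length(labels)) {
    abort("`images` and `labels` must have equal length")
  }
  if (length(class_names) < 1L) abort("`class_names` must be non-empty")
  if (length(labels) && (any(labels < 1L) ||
                         any(labels > length(class_names)))) {
    abort("labels must index into `class_names`")
  }
  if (length(provenance) == 1L) provenance <- rep(provenance, length(images))
  if (!all(provenance %in% c("original", "synthetic"))) {
    abort("provenance must be 'original' or 'synthetic'")
  }
  for (im in images) {
    d <- dim(im)
    if (length(d) != 3L || d[3] != 3L) {
      abort("every image must be an H x W x 3 array")
    }
    if (min(im) < 0 || max(im) > 255) {
      abort("image intensities must lie in [0, 255]")
    }
  }
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 provenance = provenance),
            class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$images)

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d images, %d classes\n", length(x),
              length(x$class_names)))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names),
               factor(x$provenance, levels = c("original", "synthetic")))
  print(tab)
  invisible(x)
}

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.image_set <- function(x, ...) {
  hw <- vapply(x$images, function(im) dim(im)[1:2], integer(2))
  tibble(index = seq_along(x$images),
         label = x$labels,
         class = x$class_names[x$labels],
         provenance = x$provenance,
         height = if (length(x$images)) hw[1, ] else integer(0),
         width = if (length(x$images)) hw[2, ] else integer(0))
}

# Subset an image_set by integer index vector.
subset_image_set <- function(x, idx) {
  image_set(x$images[idx], x$labels[idx], x$class_names,
            x$provenance[idx])
}
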