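# Synthetic fixtures: class-distinguishable cell-like images and separable
# Gaussian feature clouds. These stand in for a real stained-smear dataset
# so every pipeline stage can be exercised quickly and offline.

#' Generate synthetic blood-cell-like fixture images
#'
#' Renders each class as a pale textured background (mimicking cytoplasm /
#' slide background) plus `k` elliptical "nucleus" blobs for class `k`, in a
#' class-specific hue with jittered sizes, centers, and orientations.
#' Classes are therefore separable by simple color statistics, which is the
#' point: the fixtures make classifier plumbing testable without any claim
#' of biological realism.
#'
#' @param n_per_class Images per class (>= 1).
#' @param n_classes Number of classes (>= 2).
#' @param image_size `c(H, W)`, each >= 16.
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @param class_names Optional class names; defaults to `class1..classK`.
#' @return An [image_set] with `n_per_class * n_classes` images tagged
#'   `provenance = "original"`.
#' @examples
#' fx <- make_synthetic_cell_images(3, 2, c(32, 32), seed = 1)
#' table(fx$labels)
#' @export
make_synthetic_cell_images <- function(n_per_class, n_classes,
                                       image_size = c(64, 64), seed = 1,
                                       class_names = NULL) {
  n_per_class <- assert_scalar_int(n_per_class, "n_per_class")
  n_classes <- assert_scalar_int(n_classes, "n_classes", min = 2L)
  if (length(image_size) != 2L || any(image_size < 16)) {
    abort("`image_size` must be c(H, W) with both >= 16")
  }
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  class_names <- class_names %||% paste0("class", seq_len(n_classes))
  gx <- matrix(rep(seq_len(H), W), H, W)           # row coordinate
  gy <- matrix(rep(seq_len(W), each = H), H, W)    # col coordinate
  with_seed(seed, {
    images <- vector("list", n_per_class * n_classes)
    labels <- integer(n_per_class * n_classes)
    i <- 0L
    for (k in seq_len(n_classes)) {
      hue <- (k - 1) / n_classes
      blob_rgb <- grDevices::col2rgb(grDevices::hsv(hue, 0.85, 0.75)) / 255
      for (r in seq_len(n_per_class)) {
        img <- array(0, c(H, W, 3))
        base <- c(0.93, 0.88, 0.90)                # pale smear background
        for (ch in 1:3) {
          img[, , ch] <- base[ch] + matrix(runif(H * W, -0.05, 0.05), H, W)
        }
        for (blob in seq_len(k)) {
          cx <- runif(1, 0.25 * H, 0.75 * H)
          cy <- runif(1, 0.25 * W, 0.75 * W)
          rx <- max(2, (0.10 + 0.04 * runif(1)) * H)
          ry <- max(2, (0.10 + 0.04 * runif(1)) * W)
          th <- runif(1, 0, pi)
          u <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
          v <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
          mask <- (u / rx)^2 + (v / ry)^2 <= 1
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[mask] <- 0.25 * plane[mask] + 0.75 * blob_rgb[ch]
            img[, , ch] <- plane
          }
        }
        i <- i + 1L
        images[[i]] <- round(pmin(pmax(img, 0), 1) * 255)
        labels[i] <- k
      }
    }
    image_set(images, labels, class_names)
  })
}

#' Generate separable Gaussian feature clouds
#'
#' Desk-scale stand-in for backbone-extracted features: class `k` is drawn
#' from an isotropic unit-variance Gaussian centered at
#' `separation * u_k` for fixed unit directions `u_k` (the first
#' `n_classes` canonical basis vectors when `dim >= n_classes`, otherwise a
#' deterministic orthonormal-ish set). `separation = 0` gives
#' indistinguishable classes; `separation = 10` gives essentially linearly
#' separable ones.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes (>= 2).
#' @param dim Feature dimension d (>= 1).
#' @param separation Distance of each class mean from the origin (>= 0).
#' @param seed Integer seed.
#' @return A tibble with numeric columns `f1..fd` and an integer `label`
#'   column in `1:n_classes`.
#' @examples
#' make_gaussian_features(5, 2, dim = 3, separation = 4, seed = 1)
#' @export
make_gaussian_features <- function(n_per_class, n_classes, dim = 128,
                                   separation = 10, seed = 1) {
  n_per_class <- assert_scalar_int(n_per_class, "n_per_class")
  n_classes <- assert_scalar_int(n_classes, "n_classes", min = 2L)
  dim <- assert_scalar_int(dim, "dim")
  if (length(separation) != 1L || separation < 0) {
    abort("`separation` must be a single number >= 0")
  }
  if (dim >= n_classes) {
    U <- diag(1, dim)[, seq_len(n_classes), drop = FALSE]
  } else {
    # deterministic directions independent of the sampling seed
    U <- with_seed(1L, matrix(rnorm(dim * n_classes), dim, n_classes))
    U <- sweep(U, 2L, sqrt(colSums(U^2)), `/`)
  }
  n <- n_per_class * n_classes
  with_seed(seed, {
    x <- matrix(rnorm(n * dim), n, dim)
    labels <- rep(seq_len(n_classes), each = n_per_class)
    x <- x + separation * t(U[, labels, drop = FALSE])
    out <- as_tibble(as.data.frame(x), .name_repair = "minimal")
    names(out) <- paste0("f", seq_len(dim))
    out$label <- labels
    out
  })
}
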