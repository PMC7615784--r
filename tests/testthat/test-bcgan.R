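small_gan_cfg <- function(iterations = 50, seed = 7) {
  gan_config(image_size = c(16, 16), gen_blocks = 3, disc_blocks = 2,
             base_filters = 4, noise_dim = 16, iterations = iterations,
             mini_batch = 8, seed = seed)
}

one_class_images <- function(n = 20, seed = 6) {
  fx <- make_synthetic_cell_images(n, 2, c(16, 16), seed = seed)
  subset <- which(fx$labels == 1)
  image_set(fx$images[subset], rep(1L, length(subset)), fx$class_names)
}

test_that("the empirical value function matches its closed-form anchors", {
  expect_equal(gan_value(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  expect_equal(round(gan_value(0.5, 0.5), 4), -1.3863)
  eps <- 1e-7
  expect_lt(abs(gan_value(1 - eps, eps)), 1e-5)    # perfect-discriminator limit
  expect_equal(gan_value(c(0.9, 0.8), 0.1),
               (log(0.9) + log(0.8)) / 2 + log(0.9), tolerance = 1e-12)
  expect_equal(round(gan_value(c(0.9, 0.8), 0.1), 4), -0.2696)
  expect_warning(gan_value(1, 0.5), "clamped")
  # constant-D limit of the generator objective: log(1 - 0.5) per sample
  expect_equal(mean(log(1 - rep(0.5, 8))), log(0.5))
})

test_that("the value function is monotone in each score", {
  set.seed(12)
  dr <- runif(5, 0.2, 0.8)
  df <- runif(4, 0.2, 0.8)
  base <- gan_value(dr, df)
  h <- 1e-4
  for (i in seq_along(dr)) {
    up <- dr; up[i] <- up[i] + h
    expect_gt(gan_value(up, df), base)
  }
  for (i in seq_along(df)) {
    up <- df; up[i] <- up[i] + h
    expect_lt(gan_value(dr, up), base)
  }
})

test_that("generator and discriminator respect their output contracts", {
  cfg <- small_gan_cfg()
  set.seed(3)
  G <- build_generator(cfg)
  z <- matrix(rnorm(4 * cfg$noise_dim), 4, cfg$noise_dim)
  imgs <- gan_generate(list(generator = G), z)
  expect_equal(dim(imgs), c(16L, 16L, 3L, 4L))
  expect_true(all(imgs >= -1 & imgs <= 1))
  # same weights + same noise -> identical images
  imgs2 <- gan_generate(list(generator = G), z)
  expect_identical(imgs, imgs2)
  D <- build_discriminator(cfg)
  ns <- asNamespace("dlbcnet")
  scores <- ns$nn_forward(D, imgs, training = FALSE)$out
  expect_equal(dim(scores), c(4L, 1L))
  expect_true(all(scores > 0 & scores < 1))
  # unreachable sizes name the nearest valid one
  expect_error(gan_config(image_size = c(16, 16), gen_blocks = 5),
               "nearest valid")
  expect_error(gan_config(kernel_size = 3), "kernel_size")
})

test_that("an untrained discriminator cannot separate real from fake", {
  cfg <- small_gan_cfg()
  real <- one_class_images(10)
  ns <- asNamespace("dlbcnet")
  xr <- ns$images_to_batch(real) * 2 - 1
  aucs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    D <- build_discriminator(cfg)
    G <- build_generator(cfg)
    z <- matrix(rnorm(10 * cfg$noise_dim), 10, cfg$noise_dim)
    xf <- gan_generate(list(generator = G), z)
    s <- c(ns$nn_forward(D, xr, training = FALSE)$out,
           ns$nn_forward(D, xf, training = FALSE)$out)
    concordance_auc(s, rep(c(TRUE, FALSE), each = 10))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("adversarial training runs, stays finite, and is seed-reproducible", {
  real <- one_class_images()
  cfg <- small_gan_cfg(iterations = 50, seed = 7)
  pair <- train_bcgan(real, cfg)
  expect_equal(nrow(pair$loss_history), 50)
  expect_true(all(is.finite(pair$loss_history$d_loss)))
  expect_true(all(is.finite(pair$loss_history$g_loss)))
  pair2 <- train_bcgan(real, cfg)
  expect_identical(pair$loss_history, pair2$loss_history)
  expect_error(train_bcgan(one_class_images(3), cfg), "mini_batch")
})

test_that("sampling maps generated images to labeled [0, 255] sets", {
  real <- one_class_images()
  pair <- train_bcgan(real, small_gan_cfg(iterations = 5, seed = 9))
  smp <- sample_images(pair, 12, class_label = 1, seed = 4,
                       class_names = real$class_names,
                       image_size = c(24, 24))
  expect_length(smp, 12)
  expect_true(all(smp$provenance == "synthetic"))
  expect_true(all(vapply(smp$images,
                         function(im) all(dim(im) == c(24, 24, 3)) &&
                           min(im) >= 0 && max(im) <= 255, logical(1))))
  smp2 <- sample_images(pair, 12, class_label = 1, seed = 4,
                        class_names = real$class_names,
                        image_size = c(24, 24))
  expect_identical(smp$images, smp2$images)
  expect_error(sample_images(pair, 0, 1), "n")
})
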