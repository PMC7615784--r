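write_fixture_tree <- function(dir, n_per_class = 3, classes = c("a", "b")) {
  fx <- make_synthetic_cell_images(n_per_class, length(classes), c(16, 16),
                                   seed = 21, class_names = classes)
  write_image_set(fx, dir)
  fx
}

test_that("loading a class-per-subdirectory tree conserves counts and order", {
  dir <- withr::local_tempdir()
  write_fixture_tree(dir, 3, c("a", "b"))
  ds <- load_image_dataset(dir, image_size = c(16, 16))
  expect_length(ds, 6)
  expect_equal(ds$labels, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(ds$class_names, c("a", "b"))
  ds2 <- load_image_dataset(dir, image_size = c(16, 16))
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$images, ds2$images)
})

test_that("loader reports missing and empty class directories by name", {
  dir <- withr::local_tempdir()
  write_fixture_tree(dir, 2, c("a", "b"))
  expect_error(load_image_dataset(dir, c("a", "b", "ghost"),
                                  image_size = c(16, 16)),
               "ghost")
  dir.create(file.path(dir, "empty"))
  expect_error(load_image_dataset(dir, image_size = c(16, 16)), "empty")
})

test_that("stratified split honors fractions, explicit counts, and seeds", {
  fx <- make_synthetic_cell_images(10, 3, c(16, 16), seed = 4)
  sp <- split_dataset(fx, 0.7, seed = 9)
  expect_equal(as.vector(table(sp$train$labels)), rep(7L, 3))
  expect_equal(as.vector(table(sp$test$labels)), rep(3L, 3))
  # union conserves per-class counts with no overlap
  expect_equal(length(sp$train) + length(sp$test), length(fx))
  sp2 <- split_dataset(fx, 0.7, seed = 9)
  expect_identical(sp$train$images, sp2$train$images)
  sp3 <- split_dataset(fx, 0.7, seed = 10)
  expect_false(identical(sp$train$images, sp3$train$images))
  spc <- split_dataset(fx, per_class_counts = list(c(8, 2), c(5, 5),
                                                   c(1, 9)), seed = 1)
  expect_equal(as.vector(table(spc$train$labels)), c(8L, 5L, 1L))
  expect_equal(as.vector(table(spc$test$labels)), c(2L, 5L, 9L))
  expect_error(split_dataset(fx, per_class_counts = list(c(9, 2), c(5, 5),
                                                         c(1, 9))),
               "exceed")
})

test_that("reference-scale split and augmentation reproduce the mixed-dataset counts", {
  # one 3120-image class split 2184/936, then 3000 synthetics appended
  classes <- c("eosinophil", "other")
  ds <- constant_image_set(c(3120, 10), classes)
  sp <- split_dataset(ds, per_class_counts = list(c(2184, 936), c(7, 3)),
                      seed = 2)
  expect_equal(sum(sp$train$labels == 1), 2184)
  expect_equal(sum(sp$test$labels == 1), 936)
  synth <- constant_image_set(c(3000, 0), classes, provenance = "synthetic")
  mixed <- assemble_mixed_dataset(sp$train, synth)
  expect_equal(sum(mixed$labels == 1), 2184 + 3000)
  # test split untouched and entirely original
  expect_equal(sum(sp$test$labels == 1), 936)
  expect_true(all(sp$test$provenance == "original"))
})

test_that("mixed-set assembly validates provenance and class tables", {
  fx <- make_synthetic_cell_images(4, 2, c(16, 16), seed = 5)
  empty <- image_set(list(), integer(0), fx$class_names,
                     provenance = character(0))
  expect_identical(assemble_mixed_dataset(fx, empty), fx)
  wrong_class <- make_synthetic_cell_images(2, 2, c(16, 16), seed = 5,
                                            class_names = c("x", "y"))
  expect_error(assemble_mixed_dataset(fx, wrong_class), "class tables")
  not_synth <- make_synthetic_cell_images(2, 2, c(16, 16), seed = 5)
  expect_error(assemble_mixed_dataset(fx, not_synth), "synthetic")
})

test_that("image_set enforces its invariants", {
  im <- array(0, c(8, 8, 3))
  expect_error(image_set(list(im), c(1, 2), "a"), "equal length")
  expect_error(image_set(list(im), 2, "a"), "index")
  expect_error(image_set(list(array(300, c(8, 8, 3))), 1, "a"), "255")
  expect_error(image_set(list(array(0, c(8, 8))), 1, "a"), "H x W x 3")
  s <- image_set(list(im), 1, c("a", "b"))
  tb <- tibble::as_tibble(s)
  expect_equal(tb$class, "a")
  expect_equal(tb$height, 8L)
})
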