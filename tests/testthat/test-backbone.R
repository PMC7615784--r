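test_that("the head has the documented six-layer structure and size", {
  bb <- build_modified_backbone(random_trunk(2048, seed = 1), 4)
  expect_equal(bb$head_layer_names,
               c("FC128", "ReLU", "BN", "FC4", "Softmax", "Classification"))
  # 2048*128 + 128 (FC128) + 2*128 (BN) + 128*4 + 4 (FC4)
  expect_equal(backbone_trainable_params(bb), 263044)
  expect_false(bb$trainable[["trunk"]])
  expect_error(build_modified_backbone(list(foo = 1), 4), "pooled")
})

test_that("the softmax head emits probability rows", {
  fx <- make_synthetic_cell_images(3, 4, c(16, 16), seed = 2)
  bb <- build_modified_backbone(random_trunk(16, seed = 3), 4, seed = 4)
  p <- backbone_probs(bb, fx)
  expect_equal(dim(p), c(12L, 4L))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
})

test_that("fine-tuning trains only the head and reduces the loss", {
  fx <- make_synthetic_cell_images(50, 4, c(16, 16), seed = 5)
  bb <- build_modified_backbone(random_trunk(16, seed = 6), 4, seed = 7)
  trunk_before <- bb$trunk$net
  head_before <- bb$head
  cfg <- finetune_config(mini_batch = 10, max_epoch = 3,
                         learning_rate = 1e-3, seed = 8)
  ft <- finetune_backbone(bb, fx, cfg)
  # freeze contract: trunk bit-identical
  expect_identical(ft$trunk$net$layers[[1]]$params,
                   trunk_before$layers[[1]]$params)
  expect_identical(ft$trunk$net$layers[[4]]$params,
                   trunk_before$layers[[4]]$params)
  # head moved
  expect_false(identical(ft$head$layers[[1]]$params$W,
                         head_before$layers[[1]]$params$W))
  lh <- ft$loss_history
  expect_true(all(is.finite(lh$loss)))
  expect_lt(mean(lh$loss[lh$epoch == max(lh$epoch)]),
            mean(lh$loss[lh$epoch == 1]))
  expect_error(finetune_backbone(bb, subset_empty <- image_set(
    list(), integer(0), fx$class_names, character(0)), cfg), "empty")
})

test_that("fine-tune configuration defaults mirror the reference setting", {
  cfg <- finetune_config()
  expect_equal(cfg$mini_batch, 10L)
  expect_equal(cfg$max_epoch, 1L)
  expect_equal(cfg$learning_rate, 1e-4)
})

test_that("extracted features are 128-d, deterministic, and finite", {
  fx <- make_synthetic_cell_images(4, 4, c(16, 16), seed = 9)
  bb <- build_modified_backbone(random_trunk(16, seed = 10), 4, seed = 11)
  f <- extract_features(bb, fx)
  expect_equal(dim(f), c(16L, 129L))                # f1..f128 + label
  expect_named(f, c(paste0("f", 1:128), "label"))
  f2 <- extract_features(bb, fx)
  expect_identical(f, f2)
  # duplicate image gives identical rows
  dup <- image_set(fx$images[c(1, 1)], c(1L, 1L), fx$class_names)
  fd <- extract_features(bb, dup)
  expect_identical(fd[1, ], fd[2, ])
  # all-zero image stays finite
  z <- image_set(list(array(0, c(16, 16, 3))), 1L, fx$class_names)
  fz <- extract_features(bb, z)
  expect_true(all(is.finite(as.matrix(fz))))
})
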