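test_that("one-vs-rest confusion counts are exact on hand-checked cases", {
  # perfect prediction
  y <- rep(1:4, times = c(2, 3, 2, 3))
  cc <- confusion_counts(y, y, 4)
  expect_equal(cc$tp, c(2L, 3L, 2L, 3L))
  expect_equal(cc$fp, rep(0L, 4))
  expect_equal(cc$fn, rep(0L, 4))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, rep(10L, 4))
  # everything predicted as class 1 on a balanced 4 x 25 problem
  y <- rep(1:4, each = 25)
  cc <- confusion_counts(y, rep(1L, 100), 4)
  expect_equal(cc$tp[1], 25L)
  expect_equal(cc$fp[1], 75L)
  expect_equal(cc$fn[1], 0L)
  expect_equal(cc$tn[1], 0L)
  # per-class partition: TP + FN equals the class size
  expect_equal(cc$tp + cc$fn, rep(25L, 4))
  expect_error(confusion_counts(integer(0), integer(0), 4), "empty")
})

test_that("the five per-class formulas match direct arithmetic", {
  counts <- tibble::tibble(class = "a", tp = 50, fp = 10, tn = 30, fn = 10)
  m <- per_class_metrics(counts)
  expect_equal(m$accuracy, 0.80)
  expect_equal(m$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(round(m$precision, 4), 0.8333)
  expect_equal(m$specificity, 0.75)
  expect_equal(round(m$sensitivity, 4), 0.8333)
  expect_equal(round(m$f1, 4), 0.8333)
  # harmonic-mean identity holds on random counts
  set.seed(2)
  rc <- tibble::tibble(class = letters[1:6],
                       tp = sample(1:50, 6), fp = sample(1:50, 6),
                       tn = sample(1:50, 6), fn = sample(1:50, 6))
  mm <- per_class_metrics(rc)
  expect_equal(mm$f1, 2 * mm$precision * mm$sensitivity /
                 (mm$precision + mm$sensitivity), tolerance = 1e-12)
  # the published f1 rounding case: unrounded internals print 0.9316
  expect_equal(round(2 * 0.9541 * 0.9100 / (0.9541 + 0.9100), 4), 0.9316,
               tolerance = 2e-3)
})

test_that("degenerate denominators yield NaN with a warning, never zero", {
  counts <- tibble::tibble(class = "a", tp = 10, fp = 0, tn = 0, fn = 0)
  expect_warning(m <- per_class_metrics(counts), "specificity")
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$precision, 1)
  expect_true(is.nan(m$specificity))
  expect_warning(mac <- macro_average(m), "NaN")
  expect_true(is.nan(mac$specificity))
})

test_that("macro averaging is the unweighted class mean", {
  pc <- tibble::tibble(class = letters[1:4],
                       accuracy = c(95.50, 97.79, 94.68, 92.23))
  expect_equal(macro_average(pc)$accuracy, 95.05)
  same <- tibble::tibble(class = letters[1:3], f1 = rep(0.7, 3))
  expect_equal(macro_average(same)$f1, 0.7)
  expect_equal(macro_average(tibble::tibble(class = letters[1:4],
                                            accuracy = c(0, 0, 0, 100)))$accuracy,
               25)
})

test_that("run aggregation averages element-wise and matches the reference table", {
  runs <- reference_runs()
  agg <- aggregate_runs(runs)
  eos <- agg[agg$class == "eosinophil", ]
  expect_equal(round(eos$accuracy, 2), 95.50)
  lym <- agg[agg$class == "lymphocyte", ]
  expect_equal(round(lym$sensitivity, 2), 99.87)
  # single report aggregates to itself
  one <- per_class_metrics(tibble::tibble(class = c("a", "b"),
                                          tp = c(5, 4), fp = c(1, 2),
                                          tn = c(3, 3), fn = c(1, 1)))
  expect_equal(aggregate_runs(list(one)), one)
  # mismatched class tables are rejected
  two <- one
  two$class <- c("a", "c")
  expect_error(aggregate_runs(list(one, two)), "class table")
})

test_that("metrics are invariant under joint permutation of the labels", {
  set.seed(6)
  y <- sample(1:4, 80, replace = TRUE)
  p <- sample(1:4, 80, replace = TRUE)
  perm <- sample(80)
  expect_equal(per_class_metrics(confusion_counts(y, p, 4)),
               per_class_metrics(confusion_counts(y[perm], p[perm], 4)))
})

test_that("ROC AUC follows the trapezoid/concordance conventions", {
  # perfectly separating scores
  s <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(roc_auc_ovr(s, c(1, 1, 2, 2))$auc, c(1, 1))
  # constant scores: chance by the tie convention
  expect_equal(roc_auc_ovr(matrix(0.5, 4, 2), c(1, 1, 2, 2))$auc,
               c(0.5, 0.5))
  # hand-counted pairwise concordance: 3 of 4 pairs concordant
  s2 <- cbind(1 - c(0.9, 0.8, 0.7, 0.1), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(roc_auc_ovr(s2, c(2, 1, 2, 1))$auc[2], 0.75)
  # absent class
  w <- testthat::capture_warnings(a <- roc_auc_ovr(s, c(1, 1, 1, 1))$auc)
  expect_match(w, "absent", all = FALSE)
  expect_true(is.nan(a[2]))
  expect_error(roc_auc_ovr(matrix(Inf, 2, 2), c(1, 2)), "finite")
})

test_that("AUC equals the pairwise-concordance estimator on random instances", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    y <- sample(1:3, n, replace = TRUE)
    y[1:3] <- 1:3
    s <- matrix(round(rnorm(n * 3), sample(0:2, 1)), n, 3)  # force ties often
    got <- roc_auc_ovr(s, y)$auc
    for (k in 1:3) {
      expect_lt(abs(got[k] - concordance_auc(s[, k], y == k)), 1e-10)
    }
  }
})
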