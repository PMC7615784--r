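test_that("random hidden layer is uniform on [-1, 1], seeded, and well-shaped", {
  hl <- init_random_layer(6, 10, seed = 3)
  expect_equal(dim(hl$W), c(6L, 10L))
  expect_length(hl$b, 10)
  expect_identical(hl, init_random_layer(6, 10, seed = 3))
  big <- init_random_layer(500, 200, seed = 4)     # 1e5 draws
  expect_lt(abs(mean(big$W)), 0.02)
  expect_true(all(big$W >= -1 & big$W <= 1))
})

test_that("hidden_output matches the element-wise definition", {
  # zeros with zero bias: sigmoid(0) = 0.5
  hl <- init_random_layer(3, 4, seed = 1)
  H0 <- hidden_output(matrix(0, 2, 3), hl$W, rep(0, 4))
  expect_equal(as.vector(H0), rep(0.5, 8))
  # 1x1 forced case: g(2*1 - 2) = 0.5
  expect_equal(hidden_output(matrix(1), matrix(2), -2)[1, 1], 0.5)
  # loop oracle on a random 5x3 input
  set.seed(8)
  x <- matrix(rnorm(15), 5, 3)
  hl <- init_random_layer(3, 7, seed = 2)
  H <- hidden_output(x, hl$W, hl$b, "sigmoid")
  Hloop <- matrix(0, 5, 7)
  for (i in 1:5) for (j in 1:7) {
    Hloop[i, j] <- 1 / (1 + exp(-(sum(hl$W[, j] * x[i, ]) + hl$b[j])))
  }
  expect_lt(max(abs(H - Hloop)), 1e-12)
  expect_error(hidden_output(matrix(NA_real_, 1, 3), hl$W, hl$b), "NA")
  expect_error(hidden_output(matrix(0, 1, 4), hl$W, hl$b), "equal")
})

test_that("each variant attains the least-squares optimum of its design", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(10:30, 1)
    d <- sample(2:6, 1)
    Z <- sample(3:12, 1)
    m <- sample(2:4, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(seq_len(m), n, replace = TRUE)
    y[seq_len(m)] <- seq_len(m)                      # every class present
    Y <- label_matrix(y, m)
    sd <- rep * 7L
    elm <- train_elm(x, y, Z = Z, seed = sd, n_classes = m)
    rvfl <- train_rvfl(x, y, Z = Z, seed = sd, n_classes = m)
    snn <- train_snn(x, y, Z = Z, seed = sd, n_classes = m)
    H <- hidden_output(x, elm$W, elm$b)
    expect_lt(abs(elm$residual - ls_residual_oracle(H, Y)), 1e-8)
    expect_lt(abs(rvfl$residual - ls_residual_oracle(cbind(x, H), Y)), 1e-8)
    expect_lt(abs(snn$residual - ls_residual_oracle(cbind(H, 1), Y)), 1e-8)
    # nesting: wider designs cannot do worse than ELM's optimum
    expect_lte(snn$residual, elm$residual + 1e-9)
    expect_lte(rvfl$residual, elm$residual + 1e-9)
  }
})

test_that("returned ELM weights are the minimum-norm minimizer", {
  set.seed(5)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- rep(1:4, each = 5)
  m <- train_elm(x, y, Z = 30, seed = 6)           # Z > N: underdetermined
  H <- hidden_output(x, m$W, m$b)
  Y <- label_matrix(y, 4)
  expect_lt(abs(norm(H %*% m$P - Y, "F") - ls_residual_oracle(H, Y)), 1e-8)
  # any perturbation inside the null space has larger Frobenius norm
  P_alt <- m$P + MASS::Null(t(H))[, 1] %o% c(1, 0, 0, 0) * 0.1
  expect_lt(norm(H %*% P_alt - Y, "F") - norm(H %*% m$P - Y, "F"), 1e-8)
  expect_lt(norm(m$P, "F"), norm(P_alt, "F"))
})

test_that("hidden parameters are frozen and fits are permutation-invariant", {
  g <- make_gaussian_features(20, 3, dim = 4, separation = 3, seed = 9)
  m <- train_elm(g, Z = 15, seed = 31)
  ref <- init_random_layer(4, 15, seed = 31)
  expect_identical(m$W, ref$W)
  expect_identical(m$b, ref$b)
  perm <- sample(nrow(g))
  m2 <- train_elm(g[perm, ], Z = 15, seed = 31, n_classes = 3)
  expect_lt(max(abs(m$P - m2$P)), 1e-10)
  m3 <- train_snn(g, Z = 15, seed = 31)
  m4 <- train_snn(g[perm, ], Z = 15, seed = 31, n_classes = 3)
  expect_lt(max(abs(m3$P - m4$P)), 1e-10)
  expect_lt(max(abs(m3$e - m4$e)), 1e-10)
})

test_that("RVFL direct links solve exactly linear targets", {
  set.seed(14)
  x <- matrix(rnorm(40 * 6), 40, 6)
  B <- matrix(rnorm(6 * 3), 6, 3)
  Ylin <- x %*% B                                   # noiseless linear target
  y <- max.col(Ylin, ties.method = "first")
  y[1:3] <- 1:3
  # solve against the continuous target through the same design algebra
  fit <- train_rvfl(x, y, Z = 5, seed = 15, n_classes = 3)
  H <- hidden_output(x, fit$W, fit$b)
  M <- cbind(x, H)
  P <- pinv(M) %*% Ylin
  expect_lt(norm(M %*% P - Ylin, "F"), 1e-6)
  # and never worse than plain linear least squares on X
  expect_lte(norm(M %*% P - Ylin, "F"),
             ls_residual_oracle(x, Ylin) + 1e-9)
  # flag switches the design to the hidden block alone
  noDL <- train_rvfl(x, y, Z = 5, seed = 15, n_classes = 3,
                     use_direct_links = FALSE)
  Hn <- hidden_output(x, noDL$W, noDL$b)
  expect_equal(nrow(noDL$P), 5)
  expect_lt(abs(noDL$residual -
                  ls_residual_oracle(Hn, label_matrix(y, 3))), 1e-8)
})

test_that("constant-class targets are reproduced exactly", {
  set.seed(20)
  x <- matrix(rnorm(12 * 3), 12, 3)
  y <- rep(2L, 12)
  m <- train_elm(x, y, Z = 6, seed = 2, n_classes = 3)
  expect_equal(predict(m, x), rep(2L, 12))
  s <- train_snn(x, y, Z = 6, seed = 2, n_classes = 3)
  expect_equal(predict(s, x), rep(2L, 12))
  # the SNN bias alone can carry a constant target
  expect_lt(s$residual, 1e-8)
})

test_that("prediction uses argmax with lowest-index tie-breaking", {
  g <- make_gaussian_features(30, 4, dim = 8, separation = 10, seed = 16)
  m <- train_elm(g, Z = 40, seed = 17)
  O <- predict(m, g, type = "raw")
  expect_equal(predict(m, g), apply(O, 1, which.max))
  expect_gte(mean(predict(m, g) == g$label), 0.99)
  # forced tie: zero output weights make every class score identical
  m$P[] <- 0
  expect_equal(unique(predict(m, g)), 1L)
  expect_error(predict(m, g[, 1:3]), "columns")
})

test_that("models round-trip through the text archive", {
  g <- make_gaussian_features(15, 3, dim = 4, separation = 5, seed = 23)
  dir <- withr::local_tempdir()
  for (fit in list(train_elm(g, Z = 8, seed = 1),
                   train_rvfl(g, Z = 8, seed = 2),
                   train_snn(g, Z = 8, seed = 3))) {
    p <- file.path(dir, paste0(fit$variant, ".json"))
    save_rnn_model(fit, p)
    back <- load_rnn_model(p)
    expect_equal(back$P, fit$P)
    expect_identical(predict(back, g), predict(fit, g))
  }
  em <- train_etrn(g, Z = 8, seeds = 4)
  save_etrn_model(em, file.path(dir, "etrn"))
  back <- load_etrn_model(file.path(dir, "etrn"))
  expect_identical(predict(back, g), predict(em, g))
})

test_that("tidy and glance expose the solved weights and fit summary", {
  g <- make_gaussian_features(15, 3, dim = 4, separation = 5, seed = 23)
  fit <- train_snn(g, Z = 6, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), (6 + 1) * 3)              # hidden terms + bias
  expect_true("bias" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$variant, "SNN")
  expect_equal(gl$Z, 6)
})
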