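test_that("voting returns any agreed label, else the ELM prediction", {
  expect_equal(majority_vote(3, 3, 1), 3)          # ELM-RVFL agreement
  expect_equal(majority_vote(2, 4, 4), 4)          # RVFL-SNN agreement
  expect_equal(majority_vote(1, 2, 3), 1)          # three-way disagreement
  expect_equal(majority_vote(5, 5, 5), 5)          # unanimity
  expect_error(majority_vote(0, 1, 1), "range")
  expect_error(majority_vote(1, 5, 1, n_classes = 4), "range")
  expect_error(majority_vote(c(1, 2), 1, 1), "equal length")
})

test_that("voting matches a brute-force rule evaluation on all 4^3 triples", {
  grid <- expand.grid(e = 1:4, v = 1:4, s = 1:4)
  got <- majority_vote(grid$e, grid$v, grid$s, n_classes = 4)
  want <- mapply(vote_oracle, grid$e, grid$v, grid$s)
  expect_equal(got, want)
  # closure: the vote is always one of the member labels
  expect_true(all(got == grid$e | got == grid$v | got == grid$s))
  # symmetry in the RVFL/SNN slots
  expect_equal(got, majority_vote(grid$e, grid$s, grid$v, n_classes = 4))
})

test_that("agreement dominance holds on random prediction streams", {
  set.seed(33)
  for (rep in 1:20) {
    truth <- sample(1:4, 60, replace = TRUE)
    noisy <- function() ifelse(runif(60) < 0.7, truth,
                               sample(1:4, 60, replace = TRUE))
    e <- noisy(); v <- noisy(); s <- noisy()
    vote <- majority_vote(e, v, s, 4)
    two_right <- (e == truth) + (v == truth) + (s == truth) >= 2
    expect_true(all(vote[two_right] == truth[two_right]))
    expect_true(all(vote == e | vote == v | vote == s))
  }
})

test_that("the trained ensemble is accurate and deterministic on fixtures", {
  g <- make_gaussian_features(100, 4, dim = 16, separation = 10, seed = 2)
  tr <- g[rep(c(TRUE, FALSE), nrow(g) / 2), ]
  te <- g[rep(c(FALSE, TRUE), nrow(g) / 2), ]
  em <- train_etrn(tr, Z = 60, seeds = 5)
  expect_gte(mean(predict(em, tr) == tr$label), 0.95)
  expect_gte(mean(predict(em, te) == te$label), 0.95)
  em2 <- train_etrn(tr, Z = 60, seeds = 5)
  expect_identical(predict(em, te), predict(em2, te))
  # identical member seeds are legal; variants still differ
  em3 <- train_etrn(tr, Z = 60, seeds = c(5, 5, 5))
  expect_identical(em3$elm$W, em3$snn$W)
  expect_type(predict(em3, te), "integer")
  # member table view agrees with the vote
  mem <- predict(em, te, type = "members")
  expect_equal(mem$vote,
               majority_vote(mem$elm, mem$rvfl, mem$snn, 4))
})
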