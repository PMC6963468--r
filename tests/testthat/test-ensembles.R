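toy_sep <- function(n = 40, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    tibble::tibble(x1 = rnorm(n, sep * y), x2 = rnorm(n), label = y)
  })
}

# noisy XOR-ish layout: no single axis-aligned stump separates it
xor_data <- function(n = 80, seed = 2) {
  withr::with_seed(seed, {
    x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
    y <- as.integer(xor(x1 > 0, x2 > 0))
    flip <- runif(n) < 0.05
    y[flip] <- 1L - y[flip]
    tibble::tibble(x1 = x1, x2 = x2, label = y)
  })
}

test_that("a 1-member bagging ensemble without resampling equals its base", {
  d <- toy_sep()
  bag <- bagging_fit(d, base = "knn", size = 1, resample = FALSE)
  base <- knn_fit(d)
  expect_equal(predict(bag, d, type = "prob"), predict(base, d, type = "prob"))
})

test_that("bagging defaults to 10 members and averages within member range", {
  d <- toy_sep(seed = 3)
  bag <- bagging_fit(d, base = "j48", seed = 5)
  expect_length(bag$members, 10)
  pr <- predict(bag, d, type = "prob")
  member_p1 <- vapply(bag$members,
                      function(m) predict(m, d, type = "prob")$p1,
                      numeric(nrow(d)))
  expect_true(all(pr$p1 >= apply(member_p1, 1, min) - 1e-12))
  expect_true(all(pr$p1 <= apply(member_p1, 1, max) + 1e-12))
  expect_equal(pr$p0 + pr$p1, rep(1, nrow(d)))
})

test_that("AdaBoost stops after one member when it is already perfect", {
  d <- toy_sep(sep = 6, seed = 4)
  ada <- adaboost_fit(d, base = "j48", size = 10, seed = 6)
  expect_equal(ada$size, 1)
  expect_identical(predict(ada, d), d$label)
})

test_that("boosted stumps beat a single stump on XOR-like data", {
  d <- xor_data()
  stump_cv <- cross_validate(
    d, function(tr) tree_fit(tr, "j48", max_depth = 1, prune = FALSE),
    folds = 5, seed = 11)
  boost_cv <- cross_validate(
    d, function(tr) adaboost_fit(tr, base = "j48", size = 10, seed = 12,
                                 max_depth = 3, prune = FALSE),
    folds = 5, seed = 11)
  expect_gt(boost_cv$metrics$accuracy, stump_cv$metrics$accuracy)
})

test_that("AdaBoost is deterministic and keeps weights as a cascade", {
  d <- xor_data(seed = 9)
  a1 <- adaboost_fit(d, base = "j48", seed = 3, max_depth = 2, prune = FALSE)
  a2 <- adaboost_fit(d, base = "j48", seed = 3, max_depth = 2, prune = FALSE)
  expect_identical(predict(a1, d, type = "prob"), predict(a2, d, type = "prob"))
  expect_true(all(a1$alphas > 0))
  expect_equal(length(a1$alphas), length(a1$members))
})

test_that("averaging fusion is the elementwise mean of member probabilities", {
  d <- toy_sep(seed = 6)
  members <- list(knn_fit(d), tree_fit(d, "j48", seed = 1),
                  tree_fit(d, "random_tree", seed = 2), forest_fit(d, seed = 3))
  mcs <- averaging_mcs(members)
  pr <- predict(mcs, d, type = "prob")
  oracle <- rowMeans(vapply(members,
                            function(m) predict(m, d, type = "prob")$p1,
                            numeric(nrow(d))))
  expect_equal(pr$p1, oracle, tolerance = 1e-12)
  # permutation invariance of the member list
  pr2 <- predict(averaging_mcs(rev(members)), d, type = "prob")
  expect_equal(pr, pr2)
})

test_that("averaging ties resolve to class 0 and identical members collapse", {
  d <- toy_sep(seed = 8)
  m <- knn_fit(d)
  same <- averaging_mcs(list(m, m))
  expect_equal(predict(same, d, type = "prob"), predict(m, d, type = "prob"))
  # two opposed certain members average to (0.5, 0.5) -> class 0
  certain0 <- knn_fit(tibble::tibble(x1 = c(0, 1), x2 = 0, label = c(0L, 0L)), k = 1)
  certain1 <- knn_fit(tibble::tibble(x1 = c(0, 1), x2 = 0, label = c(1L, 1L)), k = 1)
  duo <- averaging_mcs(list(certain0, certain1))
  q <- tibble::tibble(x1 = 0.5, x2 = 0)
  expect_equal(as.numeric(predict(duo, q, type = "prob")), c(0.5, 0.5))
  expect_identical(predict(duo, q), 0L)
  expect_error(averaging_mcs(list(m)), ">= 2")
})
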