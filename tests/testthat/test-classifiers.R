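toy_data <- function(n = 40, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    tibble::tibble(x1 = rnorm(n, sep * y), x2 = rnorm(n), label = y)
  })
}

test_that("k-NN honours its tie and scaling contracts", {
  one <- tibble::tibble(x = 1, label = 1L)
  m1 <- knn_fit(one, k = 1)
  expect_identical(predict(m1, tibble::tibble(x = -5)), 1L)

  # two coincident points of opposite labels, k = 2: falls to class 0
  coin <- tibble::tibble(x = c(0, 0), label = c(0L, 1L))
  m2 <- knn_fit(coin, k = 2)
  expect_identical(predict(m2, tibble::tibble(x = 0)), 0L)
  expect_equal(as.numeric(predict(m2, tibble::tibble(x = 0), type = "prob")),
               c(0.5, 0.5))

  # query at a training point with k = 1 recovers its class with certainty
  d <- toy_data()
  m3 <- knn_fit(d, k = 1)
  p <- predict(m3, d[3, ], type = "prob")
  expect_equal(p$p0, 1)
  expect_error(knn_fit(d, k = 99), "k")
})

test_that("k-NN equals the brute-force all-pairs oracle", {
  d <- toy_data(n = 60, sep = 1, seed = 7)
  withr::with_seed(8, {
    q <- tibble::tibble(x1 = rnorm(50, 0.5), x2 = rnorm(50))
  })
  for (k in c(1, 2, 3)) {
    m <- knn_fit(d, k = k)
    got <- predict(m, q)
    want <- knn_oracle(as.matrix(d[c("x1", "x2")]), d$label,
                       as.matrix(q), k)
    expect_identical(got, as.integer(want))
    pr <- predict(m, q, type = "prob")
    expect_equal(pr$p0 + pr$p1, rep(1, nrow(q)))
  }
})

test_that("trees reduce to a single leaf on pure data", {
  pure <- tibble::tibble(x = 1:10, label = rep(1L, 10))
  m <- tree_fit(pure, "j48")
  expect_true(m$root$leaf)
  expect_identical(predict(m, pure), rep(1L, 10))
})

test_that("j48 separates 1-D threshold data with one split between classes", {
  withr::with_seed(5, {
    x <- c(runif(10, -2, -0.2), runif(10, 0.2, 2))
  })
  d <- tibble::tibble(x = x, label = rep(c(0L, 1L), each = 10))
  m <- tree_fit(d, "j48", prune = FALSE)
  expect_false(m$root$leaf)
  expect_true(m$root$left$leaf && m$root$right$leaf)
  expect_gt(m$root$threshold, max(x[1:10]))
  expect_lt(m$root$threshold, min(x[11:20]))
  expect_identical(predict(m, d), d$label)
})

test_that("the root gain ratio matches a hand-computed oracle", {
  # 4-point table: x = 1,2,3,4 with labels 0,0,1,1; best cut at 2.5
  d <- tibble::tibble(x = 1:4, label = c(0L, 0L, 1L, 1L))
  m <- tree_fit(d, "j48", prune = FALSE)
  expect_equal(m$root$threshold, 2.5)
  s <- mammocad:::best_split_feature(d$x, d$label)
  # parent entropy 1 bit; perfect halves: gain = 1, split info = 1
  expect_equal(s$gain, 1)
  expect_equal(s$ratio, 1)
  # an imperfect table, checked against the explicit formula
  d2 <- tibble::tibble(x = c(1, 2, 3, 4), label = c(0L, 1L, 1L, 1L))
  s2 <- mammocad:::best_split_feature(d2$x, d2$label)
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  gain_cut1 <- h(3 / 4) - (1 / 4) * 0 - (3 / 4) * 0
  split_info_cut1 <- h(1 / 4)
  expect_equal(s2$ratio, gain_cut1 / split_info_cut1)
})

test_that("training accuracy is non-decreasing in the depth cap", {
  d <- toy_data(n = 60, sep = 1.2, seed = 9)
  accs <- vapply(c(1, 2, 4, 8), function(dep) {
    m <- tree_fit(d, "j48", max_depth = dep, prune = FALSE)
    mean(predict(m, d) == d$label)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("random trees and forests are seed-deterministic", {
  d <- toy_data(n = 40, sep = 1, seed = 10)
  m1 <- tree_fit(d, "random_tree", seed = 3)
  m2 <- tree_fit(d, "random_tree", seed = 3)
  expect_identical(predict(m1, d, type = "prob"), predict(m2, d, type = "prob"))

  f1 <- forest_fit(d, seed = 4)
  f2 <- forest_fit(d, seed = 4)
  expect_equal(f1$n_trees, 10)
  expect_identical(predict(f1, d, type = "prob"), predict(f2, d, type = "prob"))
})

test_that("a 1-tree forest without bootstrap equals its single random tree", {
  d <- toy_data(n = 40, sep = 2, seed = 11)
  f <- forest_fit(d, n_trees = 1, seed = 6, bootstrap = FALSE)
  t1 <- tree_fit(d, "random_tree", seed = mammocad:::derive_seed(6L, 1))
  expect_equal(predict(f, d, type = "prob"), predict(t1, d, type = "prob"))
})

test_that("prediction is the argmax of the probabilities for every kind", {
  d <- toy_data(n = 40, sep = 1, seed = 12)
  for (kind in c("knn", "j48", "random_tree", "random_forest")) {
    m <- fit_classifier(d, kind, seed = 2)
    pr <- predict(m, d, type = "prob")
    cls <- predict(m, d)
    # on exact probability ties k-NN defers to its nearer-neighbour rule;
    # everywhere else the hard class is the probability argmax
    untied <- pr$p1 != 0.5
    expect_identical(cls[untied], as.integer(pr$p1 > 0.5)[untied])
    if (kind != "knn") expect_identical(cls, as.integer(pr$p1 > 0.5))
  }
})
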