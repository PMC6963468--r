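test_that("confusion metrics follow the defining ratios", {
  perfect <- metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(as.numeric(perfect[1:5]), rep(1, 5))

  m <- metrics(list(TP = 45, TN = 40, FP = 10, FN = 5))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$precision, 45 / 55)
  expect_equal(m$f1, 2 * (45 / 55) * 0.9 / ((45 / 55) + 0.9))
  # complement identity: sensitivity + FNR = 1
  expect_equal(m$sensitivity + 5 / (45 + 5), 1)
  # accuracy decomposes by class prevalence
  expect_equal(m$accuracy, (0.9 * 50 + 0.8 * 50) / 100)
})

test_that("zero-denominator metrics report 0 with an undefined flag", {
  m <- metrics(list(TP = 0, TN = 10, FP = 0, FN = 5))
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_true("precision" %in% m$undefined[[1]])
  expect_error(metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("AUC equals the all-pairs Mann-Whitney oracle", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(3, {
    y <- rep(c(0L, 1L), each = 100)
    s <- round(runif(200), 2)          # coarse scores force ties
  })
  expect_equal(roc_auc(s, y), auc_oracle(s, y), tolerance = 1e-14)
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(3 * s), y), roc_auc(s, y))
  expect_error(roc_auc(s, rep(1, 200)), "both classes")
  # cross-check against an established ROC implementation
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("stratified five-fold CV makes an 80-20 partition", {
  d <- make_informative_dataset(n = 100, n_noise = 2, seed = 4)
  cv <- cross_validate(d, function(tr) knn_fit(tr, k = 2), folds = 5, seed = 9)
  expect_equal(as.numeric(table(cv$fold_id)), rep(20, 5))
  expect_setequal(unique(cv$fold_id), 1:5)
  # per-class stratification
  expect_true(all(table(cv$fold_id, d$label) == 10))
  # pooled accuracy equals the sample-weighted mean of fold accuracies
  per <- tidy(cv)
  expect_equal(cv$metrics$accuracy, mean(per$accuracy))
  expect_equal(glance(cv)$auc, cv$auc)
  expect_error(cross_validate(d[1:6, ], function(tr) knn_fit(tr, k = 1),
                              folds = 5), "fewer")
})

test_that("CV on label-independent features stays near the majority rate", {
  withr::with_seed(11, {
    d <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100),
                        label = rep(c(0L, 1L), each = 50))
  })
  cv <- cross_validate(d, function(tr) knn_fit(tr, k = 2), folds = 5, seed = 13)
  expect_lt(abs(cv$metrics$accuracy - 0.5), 0.1)
})

test_that("nested selection reduces to plain CV for a single candidate", {
  d <- make_informative_dataset(n = 60, n_noise = 2, seed = 6)
  fac <- function(k) function(tr) knn_fit(tr, k = k)
  ns <- nested_select(d, fac, candidates = list(2), outer = 5, inner = 3,
                      seed = 21)
  cv <- cross_validate(d, fac(2), folds = 5, seed = 21)
  expect_equal(ns$metrics$accuracy, cv$metrics$accuracy)
  expect_equal(nrow(ns$choices), 5)
})

test_that("nested k selection tracks the best plain-CV candidate closely", {
  d <- make_informative_dataset(n = 80, n_noise = 3, shift = 1.5, seed = 7)
  fac <- function(k) function(tr) knn_fit(tr, k = k)
  ks <- c(1, 2, 3, 5)
  ns <- nested_select(d, fac, candidates = as.list(ks), outer = 5, inner = 3,
                      seed = 23)
  plain <- vapply(ks, function(k) {
    cross_validate(d, fac(k), folds = 5, seed = 23)$metrics$accuracy
  }, numeric(1))
  expect_gte(ns$metrics$accuracy, max(plain) - 0.05)
  expect_true(all(unlist(ns$choices$candidate) %in% ks))
})

test_that("ROC points run from the all-negative to all-positive corner", {
  withr::with_seed(15, {
    y <- rep(c(0L, 1L), each = 20)
    s <- runif(40) + 0.3 * y
  })
  pts <- roc_points(s, y)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})
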