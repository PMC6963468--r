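# Multiple-classifier systems: bagging (parallel), AdaBoost.M1 with
# weight-proportional resampling (cascaded), and averaging fusion across
# heterogeneous classifiers.

#' Fit a bagging ensemble
#'
#' Trains `size` base classifiers, each on an n-row bootstrap resample of the
#' training data, and averages their class probabilities. Any base kind of
#' [fit_classifier()] can be bagged (including k-NN, which has no training
#' error surface of its own: the resampling is what diversifies members).
#'
#' @param data Data frame with numeric features and a binary label column.
#' @param base Base classifier kind (see [fit_classifier()]).
#' @param size Member count (default 10).
#' @param seed Integer RNG seed.
#' @param resample Bootstrap members (default TRUE); `size = 1` with
#'   `resample = FALSE` reduces to the base classifier.
#' @param ... Passed to [fit_classifier()].
#' @param label_col Name of the label column.
#' @return A fitted `bagging_model`.
#' @export
bagging_fit <- function(data, base = "j48", size = 10, seed = 1L,
                        resample = TRUE, ..., label_col = "label") {
  n <- nrow(data)
  if (n < 2) stop("need at least two training rows", call. = FALSE)
  member_seeds <- vapply(seq_len(size), function(i) derive_seed(seed, 100 + i),
                         integer(1))
  members <- withr::with_seed(seed, {
    lapply(seq_len(size), function(i) {
      rows <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
      fit_classifier(data[rows, , drop = FALSE], kind = base,
                     seed = member_seeds[i], ..., label_col = label_col)
    })
  })
  structure(
    list(kind = "bagging", base = base, members = members, size = size,
         feature_names = members[[1]]$feature_names, label_col = label_col),
    class = c("bagging_model", "mc_model"))
}

#' @export
predict.bagging_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  average_members(object$members, newdata, type)
}

average_members <- function(members, newdata, type) {
  nq <- nrow(as.data.frame(newdata))
  probs <- vapply(members, function(m) predict(m, newdata, type = "prob")$p1,
                  numeric(nq))
  p1 <- if (is.matrix(probs)) rowMeans(probs) else mean(probs)
  res <- cbind(1 - p1, p1, as.integer(p1 > 0.5))  # tie -> class 0
  finish_prediction(res, type)
}

#' Fit an AdaBoost.M1 ensemble
#'
#' Cascaded boosting with weight-proportional resampling: instance weights
#' start uniform; each round fits the base classifier on a resample drawn
#' with the current weights, computes the weighted training error
#' `eps`, stops early when `eps = 0` (the member is kept) or `eps >= 0.5`
#' (the member is dropped; if that happens in round 1 the ensemble degrades
#' to that single member with unit weight, with a warning), otherwise sets
#' the member weight `alpha = 0.5 * log((1 - eps) / eps)`, multiplies
#' misclassified-instance weights by `exp(alpha)`, and renormalizes. The
#' decision is the sign of the alpha-weighted +/-1 vote sum; the class-1
#' probability is the logistic of the normalized margin (a monotone score in
#' `[plogis(-1), plogis(1)]` suitable for ROC analysis).
#'
#' @inheritParams bagging_fit
#' @return A fitted `adaboost_model` with per-member `alpha` weights.
#' @export
adaboost_fit <- function(data, base = "j48", size = 10, seed = 1L, ...,
                         label_col = "label") {
  n <- nrow(data)
  if (n < 2) stop("need at least two training rows", call. = FALSE)
  y <- assert_labels(data[[label_col]])
  w <- rep(1 / n, n)
  members <- list(); alphas <- numeric(0)
  withr::with_seed(seed, {
    for (t in seq_len(size)) {
      rows <- sample.int(n, n, replace = TRUE, prob = w)
      m <- fit_classifier(data[rows, , drop = FALSE], kind = base,
                          seed = derive_seed(seed, 200 + t), ...,
                          label_col = label_col)
      pred <- predict(m, data, type = "class")
      miss <- pred != y
      eps <- sum(w[miss])
      if (eps >= 0.5) {
        if (t == 1L) {
          warning("base classifier no better than chance in round 1; ",
                  "ensemble reduced to that single member", call. = FALSE)
          members[[1]] <- m; alphas[1] <- 1
        }
        break
      }
      if (eps == 0) {
        members[[t]] <- m
        alphas[t] <- 0.5 * log((1 - 1e-10) / 1e-10)
        break
      }
      alpha <- 0.5 * log((1 - eps) / eps)
      members[[t]] <- m; alphas[t] <- alpha
      w[miss] <- w[miss] * exp(alpha)
      w <- w / sum(w)
    }
  })
  structure(
    list(kind = "adaboost", base = base, members = members, alphas = alphas,
         size = length(members),
         feature_names = members[[1]]$feature_names, label_col = label_col),
    class = c("adaboost_model", "mc_model"))
}

#' @export
predict.adaboost_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  nq <- nrow(as.data.frame(newdata))
  votes <- vapply(object$members,
                  function(m) 2 * as.numeric(predict(m, newdata, type = "class")) - 1,
                  numeric(nq))
  if (!is.matrix(votes)) votes <- matrix(votes, nrow = nq)
  margin <- as.numeric(votes %*% object$alphas) / sum(object$alphas)
  p1 <- plogis(margin)
  cls <- as.integer(margin > 0)    # sign rule; zero margin -> class 0
  finish_prediction(cbind(1 - p1, p1, cls), type)
}

#' Averaging-fusion multiple classifier system
#'
#' Combines two or more fitted heterogeneous classifiers by unweighted
#' averaging of their class-probability rows; the hard prediction is the
#' argmax with ties to class 0.
#'
#' @param members List of at least two fitted models sharing one feature
#'   space.
#' @return A fitted `averaging_model`.
#' @export
averaging_mcs <- function(members) {
  if (length(members) < 2) stop("averaging fusion needs >= 2 members", call. = FALSE)
  fn <- members[[1]]$feature_names
  same <- vapply(members, function(m) identical(m$feature_names, fn), logical(1))
  if (!all(same)) {
    stop("members disagree on the feature space", call. = FALSE)
  }
  structure(
    list(kind = "averaging", members = members, size = length(members),
         feature_names = fn, label_col = members[[1]]$label_col),
    class = c("averaging_model", "mc_model"))
}

#' @export
predict.averaging_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  average_members(object$members, newdata, type)
}
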