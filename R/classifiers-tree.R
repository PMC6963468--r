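# Gain-ratio decision trees: a C4.5-style greedy tree ("j48"), a
# random-feature tree ("random_tree"), and a bootstrap forest of random trees.

entropy_bits <- function(y) {
  if (length(y) == 0) return(0)
  p <- tabulate(y + 1L, nbins = 2L) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Best threshold for one numeric feature by gain ratio; candidate thresholds
# are midpoints between consecutive distinct sorted values. Returns NULL when
# no split has positive information gain.
best_split_feature <- function(x, y) {
  n <- length(y)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cut_at <- which(xs[-1] > xs[-n])     # boundary after position i
  if (length(cut_at) == 0) return(NULL)
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  nl <- cut_at
  n1l <- cum1[cut_at]
  nr <- n - nl
  n1r <- n1 - n1l
  h2 <- function(k, m) {             # entropy of a binary split of size m
    p <- k / m
    out <- numeric(length(p))
    ok <- p > 0 & p < 1
    out[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
    out
  }
  gain <- entropy_bits(y) - (nl / n) * h2(n1l, nl) - (nr / n) * h2(n1r, nr)
  split_info <- h2(nl, n)
  ok <- gain > 1e-12 & split_info > 0
  if (!any(ok)) return(NULL)
  ratio <- ifelse(ok, gain / split_info, -Inf)
  best <- which.max(ratio)           # earliest (lowest threshold) on ties
  list(threshold = (xs[cut_at[best]] + xs[cut_at[best] + 1]) / 2,
       ratio = ratio[best], gain = gain[best])
}

grow_tree <- function(X, y, kind, min_leaf, max_depth, depth = 0L) {
  n <- length(y)
  prob <- tabulate(y + 1L, nbins = 2L) / n
  leaf <- list(leaf = TRUE, prob = prob, n = n)
  if (n < min_leaf || length(unique(y)) == 1L || depth >= max_depth) return(leaf)
  d <- ncol(X)
  cand <- if (kind == "random_tree") {
    m <- min(d, as.integer(ceiling(log2(d) + 1)))
    sort(sample.int(d, m))
  } else {
    seq_len(d)
  }
  best <- NULL
  for (j in cand) {
    s <- best_split_feature(X[, j], y)
    if (!is.null(s) && (is.null(best) || s$ratio > best$ratio + 1e-12)) {
      best <- c(s, feature = j)      # strict improvement => lowest index wins ties
    }
  }
  if (is.null(best)) return(leaf)
  go_left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       prob = prob, n = n,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left],
                        kind, min_leaf, max_depth, depth + 1L),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left],
                         kind, min_leaf, max_depth, depth + 1L))
}

# Reduced-error pruning: collapse any internal node whose subtree does not
# beat the node-as-leaf error on the validation split.
prune_tree <- function(node, Xv, yv) {
  if (node$leaf || length(yv) == 0) return(node)
  go_left <- Xv[, node$feature] <= node$threshold
  node$left <- prune_tree(node$left, Xv[go_left, , drop = FALSE], yv[go_left])
  node$right <- prune_tree(node$right, Xv[!go_left, , drop = FALSE], yv[!go_left])
  pred_sub <- tree_route(node, Xv)
  err_sub <- sum((pred_sub >= 0.5) != yv)
  leaf_cls <- as.integer(node$prob[2] >= 0.5)
  err_leaf <- sum(leaf_cls != yv)
  if (err_leaf <= err_sub) {
    return(list(leaf = TRUE, prob = node$prob, n = node$n))
  }
  node
}

# Vectorized routing: per-row probability of class 1.
tree_route <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  recurse <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$prob[2]; return() }
    go_left <- X[idx, node$feature] <= node$threshold
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  recurse(node, seq_len(n))
  out
}

#' Fit a gain-ratio decision tree
#'
#' Greedy top-down binary splits on numeric features, choosing at each node
#' the threshold (a midpoint between consecutive distinct values) that
#' maximizes the gain ratio; nodes stop splitting when pure, smaller than
#' `min_leaf`, at `max_depth`, or when no split has positive information
#' gain. Leaf probabilities are the class frequencies at the leaf.
#'
#' Two kinds are available: `"j48"` considers every feature at each node and
#' by default applies reduced-error pruning against an internal stratified
#' 25% validation split; `"random_tree"` considers only
#' `ceiling(log2(d) + 1)` uniformly sampled features per node and never
#' prunes.
#'
#' @param data Data frame with numeric features and a binary label column.
#' @param kind `"j48"` or `"random_tree"`.
#' @param min_leaf Minimum node size to attempt a split (default 2).
#' @param max_depth Depth cap (default unlimited; 1 gives a decision stump).
#' @param prune Reduced-error pruning (default TRUE for `"j48"`, ignored for
#'   `"random_tree"`).
#' @param seed Seed for the pruning split and random feature draws.
#' @param label_col Name of the label column.
#' @return A fitted `tree_model`.
#' @export
tree_fit <- function(data, kind = c("j48", "random_tree"), min_leaf = 2,
                     max_depth = Inf, prune = NULL, seed = 1L,
                     label_col = "label") {
  kind <- match.arg(kind)
  d <- split_xy(data, label_col)
  if (nrow(d$X) < 1) stop("empty training data", call. = FALSE)
  if (is.null(prune)) prune <- kind == "j48"
  if (kind == "random_tree") prune <- FALSE
  root <- withr::with_seed(seed, {
    if (prune && length(unique(d$y)) > 1L && nrow(d$X) >= 8) {
      vid <- stratified_split(d$y, frac = 0.25)
      r <- grow_tree(d$X[!vid, , drop = FALSE], d$y[!vid], kind, min_leaf, max_depth)
      prune_tree(r, d$X[vid, , drop = FALSE], d$y[vid])
    } else {
      grow_tree(d$X, d$y, kind, min_leaf, max_depth)
    }
  })
  structure(
    list(kind = kind, root = root, feature_names = d$feature_names,
         label_col = label_col, min_leaf = min_leaf, max_depth = max_depth,
         pruned = prune),
    class = c("tree_model", "mc_model"))
}

# Stratified logical holdout indicator covering ~frac of each class.
stratified_split <- function(y, frac) {
  vid <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    take <- max(1L, floor(length(idx) * frac))
    vid[sample(idx, take)] <- TRUE
  }
  vid
}

#' @export
predict.tree_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Xq <- query_matrix(object, newdata)
  p1 <- tree_route(object$root, Xq)
  res <- cbind(1 - p1, p1, as.integer(p1 > 0.5))  # tie -> lower class index
  finish_prediction(res, type)
}

#' Fit a random forest of gain-ratio random trees
#'
#' Fits `n_trees` unpruned random-feature trees, each on a bootstrap
#' resample of the training rows (n draws with replacement); the forest
#' probability is the mean of the member probabilities. Deterministic given
#' `seed`.
#'
#' @param data Data frame with numeric features and a binary label column.
#' @param n_trees Number of member trees (default 10).
#' @param seed Integer RNG seed.
#' @param bootstrap Draw bootstrap resamples (default TRUE); with
#'   `bootstrap = FALSE` every member sees the full data.
#' @param min_leaf,max_depth Passed to each member tree.
#' @param label_col Name of the label column.
#' @return A fitted `forest_model`.
#' @export
forest_fit <- function(data, n_trees = 10, seed = 1L, bootstrap = TRUE,
                       min_leaf = 2, max_depth = Inf, label_col = "label") {
  n <- nrow(data)
  if (n < 2) stop("need at least two training rows", call. = FALSE)
  member_seeds <- vapply(seq_len(n_trees), function(i) derive_seed(seed, i),
                         integer(1))
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tree_fit(data[rows, , drop = FALSE], kind = "random_tree",
               min_leaf = min_leaf, max_depth = max_depth,
               seed = member_seeds[i], label_col = label_col)
    })
  })
  structure(
    list(kind = "random_forest", trees = trees, n_trees = n_trees,
         feature_names = trees[[1]]$feature_names, label_col = label_col),
    class = c("forest_model", "mc_model"))
}

#' @export
predict.forest_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- vapply(object$trees,
                  function(tr) predict(tr, newdata, type = "prob")$p1,
                  numeric(nrow(as.data.frame(newdata))))
  p1 <- if (is.matrix(probs)) rowMeans(probs) else mean(probs)
  res <- cbind(1 - p1, p1, as.integer(p1 > 0.5))
  finish_prediction(res, type)
}

#' Fit any of the pipeline's individual classifiers
#'
#' Dispatch helper used by cross-validation and feature selection: fits a
#' classifier of the given kind with the pipeline defaults (k = 2
#' neighbours, 10 forest trees).
#'
#' @param data Data frame with numeric features and a binary label column.
#' @param kind One of `"knn"`, `"j48"`, `"random_tree"`, `"random_forest"`.
#' @param seed Integer RNG seed for the stochastic kinds.
#' @param ... Passed on to the specific fitting function.
#' @param label_col Name of the label column.
#' @return A fitted model.
#' @export
fit_classifier <- function(data, kind = c("knn", "j48", "random_tree",
                                          "random_forest"),
                           seed = 1L, ..., label_col = "label") {
  kind <- match.arg(kind)
  switch(kind,
    knn = knn_fit(data, label_col = label_col, ...),
    j48 = tree_fit(data, kind = "j48", seed = seed, label_col = label_col, ...),
    random_tree = tree_fit(data, kind = "random_tree", seed = seed,
                           label_col = label_col, ...),
    random_forest = forest_fit(data, seed = seed, label_col = label_col, ...))
}
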