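# Wrapper feature selection over the feature columns: the objective is the
# stratified cross-validated accuracy of a chosen classifier on the
# column-restricted data. Fold assignments are drawn once per search and
# memoized per subset, so re-evaluating a subset is free and deterministic.

new_fs_cache <- function(data, kind, cv_folds, seed, label_col, ...) {
  force(data)
  extra <- list(...)
  env <- new.env(parent = emptyenv())
  feature_cols <- setdiff(names(data), label_col)
  fit_seed <- derive_seed(seed, 7)
  objective <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(env[[key]])) return(env[[key]])
    sub_data <- data[c(subset, label_col)]
    fit <- function(d) do.call(fit_classifier,
                               c(list(data = d, kind = kind, seed = fit_seed,
                                      label_col = label_col), extra))
    cv <- cross_validate(sub_data, fit, folds = cv_folds, seed = seed,
                         label_col = label_col)
    env[[key]] <- cv$metrics$accuracy
    env[[key]]
  }
  list(objective = objective, cache = env, feature_cols = feature_cols)
}

#' Cross-validated objective of a feature subset
#'
#' Mean stratified k-fold CV accuracy of the classifier trained on the
#' column-restricted data. Restricting to the full feature set reproduces
#' the plain CV accuracy of the classifier; the fold split depends only on
#' the seed, so identical subsets always score identically.
#'
#' @param data Data frame with numeric features and a binary label column.
#' @param subset Nonempty character vector of feature column names.
#' @param kind Classifier kind (see [fit_classifier()]).
#' @param cv_folds Number of folds (default 5).
#' @param seed Integer seed (folds and any classifier randomness).
#' @param label_col Name of the label column.
#' @param ... Passed to [fit_classifier()].
#' @return Accuracy fraction in `[0, 1]`.
#' @export
subset_objective <- function(data, subset, kind = "knn", cv_folds = 5,
                             seed = 1L, label_col = "label", ...) {
  if (length(subset) == 0) stop("subset must be nonempty", call. = FALSE)
  bad <- setdiff(subset, names(data))
  if (length(bad)) {
    stop(sprintf("unknown features: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cache <- new_fs_cache(data, kind, cv_folds, seed, label_col, ...)
  cache$objective(subset)
}

fs_result <- function(selected, objective, trace, method) {
  structure(
    list(selected = selected, objective = objective, trace = trace,
         n_evaluated = nrow(trace), method = method),
    class = "fs_result")
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("<fs_result> %s: %d/%d evaluations, objective %.4f\n  selected: %s\n",
              x$method, x$n_evaluated, nrow(x$trace), x$objective,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

# Deterministic preference between equal-objective subsets: higher objective,
# then smaller subset, then lexicographic order of the sorted feature names.
better_subset <- function(obj_a, sub_a, obj_b, sub_b) {
  if (obj_a != obj_b) return(obj_a > obj_b)
  if (length(sub_a) != length(sub_b)) return(length(sub_a) < length(sub_b))
  paste(sort(sub_a), collapse = "|") < paste(sort(sub_b), collapse = "|")
}

#' Best-first wrapper feature selection
#'
#' Greedy best-first search over the subset lattice: an open list ordered by
#' objective is repeatedly popped, and the popped subset is expanded into
#' its single-feature additions and (bidirectional search) deletions.
#' Backtracking is implicit — the open list retains earlier promising
#' subsets, so the search returns to them whenever the current track stops
#' improving. The search stops after `stale_limit` consecutive expansions
#' without a new global best (or when the open list is exhausted, which for
#' `stale_limit = Inf` on d <= 8 means every nonempty subset was scored).
#' Equal objectives prefer the smaller, then lexicographically first subset.
#'
#' @inheritParams subset_objective
#' @param direction `"bidirectional"` (additions and deletions, default),
#'   `"forward"` (additions only) or `"backward"` (deletions only).
#' @param stale_limit Consecutive non-improving expansions tolerated
#'   (default 5; `Inf` exhausts the lattice).
#' @return An `fs_result`: `selected`, `objective`, the evaluation `trace`
#'   tibble, and `n_evaluated`.
#' @export
best_first_search <- function(data, kind = "knn", cv_folds = 5, seed = 1L,
                              direction = c("bidirectional", "forward",
                                            "backward"),
                              stale_limit = 5, label_col = "label", ...) {
  direction <- match.arg(direction)
  cache <- new_fs_cache(data, kind, cv_folds, seed, label_col, ...)
  feats <- cache$feature_cols
  d <- length(feats)
  stopifnot(d >= 1)

  trace <- list()
  evaluated <- character(0)
  score <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    obj <- cache$objective(subset)
    if (!key %in% evaluated) {
      evaluated <<- c(evaluated, key)
      trace[[length(trace) + 1]] <<- tibble::tibble(
        subset = list(sort(subset)), size = length(subset), objective = obj)
    }
    obj
  }

  # start: all singletons (forward/bidirectional) or the full set (backward)
  start_sets <- if (direction == "backward") list(feats) else
    lapply(feats, function(f) f)
  open <- list()
  push <- function(subset, obj) {
    key <- paste(sort(subset), collapse = "|")
    if (key %in% vapply(open, function(o) o$key, character(1))) return()
    open[[length(open) + 1]] <<- list(subset = subset, obj = obj, key = key)
  }
  expanded <- character(0)
  for (s in start_sets) push(s, score(s))

  best_sub <- NULL; best_obj <- -Inf
  for (o in open) {
    if (is.null(best_sub) || better_subset(o$obj, o$subset, best_obj, best_sub)) {
      best_sub <- o$subset; best_obj <- o$obj
    }
  }
  stale <- 0
  while (length(open) > 0 && stale < stale_limit) {
    # pop the best unexpanded node
    objs <- vapply(open, function(o) o$obj, numeric(1))
    sizes <- vapply(open, function(o) length(o$subset), numeric(1))
    keys <- vapply(open, function(o) o$key, character(1))
    pick <- order(-objs, sizes, keys)[1]
    node <- open[[pick]]
    open[[pick]] <- NULL
    if (node$key %in% expanded) next
    expanded <- c(expanded, node$key)

    neighbors <- list()
    if (direction %in% c("bidirectional", "forward")) {
      for (f in setdiff(feats, node$subset)) {
        neighbors <- c(neighbors, list(c(node$subset, f)))
      }
    }
    if (direction %in% c("bidirectional", "backward") && length(node$subset) > 1) {
      for (f in node$subset) {
        neighbors <- c(neighbors, list(setdiff(node$subset, f)))
      }
    }
    improved <- FALSE
    for (nb in neighbors) {
      key <- paste(sort(nb), collapse = "|")
      obj <- score(nb)
      if (!key %in% expanded) push(nb, obj)
      if (better_subset(obj, nb, best_obj, best_sub)) {
        best_sub <- nb; best_obj <- obj; improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
  }
  fs_result(sort(best_sub), best_obj, dplyr::bind_rows(trace),
            paste0("best_first_", direction))
}

#' Random-search wrapper feature selection
#'
#' Starts from a uniformly random nonempty subset and then evaluates
#' `budget` distinct subsets drawn at random — alternating uniformly random
#' subsets with single-feature mutations of the best subset so far — keeping
#' the best. Already-scored subsets are deduplicated and do not consume
#' budget; if the budget reaches the number of nonempty subsets
#' (`2^d - 1`), the search is exhaustive. Deterministic under `seed`.
#'
#' @inheritParams subset_objective
#' @param budget Number of distinct subset evaluations (default 100),
#'   including the random start.
#' @return An `fs_result`.
#' @export
random_search <- function(data, kind = "knn", cv_folds = 5, seed = 1L,
                          budget = 100, label_col = "label", ...) {
  stopifnot(budget >= 1)
  cache <- new_fs_cache(data, kind, cv_folds, seed, label_col, ...)
  feats <- cache$feature_cols
  d <- length(feats)
  total <- 2^d - 1
  budget <- min(budget, total)

  trace <- list()
  seen <- character(0)
  score <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    obj <- cache$objective(subset)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      trace[[length(trace) + 1]] <<- tibble::tibble(
        subset = list(sort(subset)), size = length(subset), objective = obj)
    }
    obj
  }
  rand_subset <- function() {
    repeat {
      keep <- runif(d) < 0.5
      if (any(keep)) return(feats[keep])
    }
  }
  first_unseen <- function(feats, seen) {
    d <- length(feats)
    for (m in seq_len(2^d - 1)) {
      sub <- feats[bitwAnd(m, 2^(seq_len(d) - 1)) > 0]
      if (!paste(sort(sub), collapse = "|") %in% seen) return(sub)
    }
    feats
  }
  withr::with_seed(derive_seed(seed, 31), {
    start <- rand_subset()
    best_sub <- start; best_obj <- score(start)
    misses <- 0L
    while (length(seen) < budget) {
      cand <- if (misses > 50L && d <= 16) {
        # rare tail case near exhaustion: take the first unseen subset
        first_unseen(feats, seen)
      } else if (runif(1) < 0.5) {
        rand_subset()
      } else {
        f <- sample(feats, 1)
        nb <- if (f %in% best_sub) setdiff(best_sub, f) else c(best_sub, f)
        if (length(nb) == 0) rand_subset() else nb
      }
      if (paste(sort(cand), collapse = "|") %in% seen) { misses <- misses + 1L; next }
      misses <- 0L
      obj <- score(cand)
      if (better_subset(obj, cand, best_obj, best_sub)) {
        best_sub <- cand; best_obj <- obj
      }
    }
  })
  fs_result(sort(best_sub), best_obj, dplyr::bind_rows(trace), "random_search")
}
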