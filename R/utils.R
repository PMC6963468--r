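# Internal helpers shared across the pipeline.

# Canonical order of the 8 per-image features. Fixed so CSV schemas and
# feature-subset encodings are deterministic.
FEATURE_NAMES <- c("entropy", "mean", "variance", "sd",
                   "range", "minimum", "maximum", "rms")

#' Canonical feature names
#'
#' The eight per-image features in their canonical order:
#' entropy, mean, variance, sd, range, minimum, maximum, rms.
#'
#' @return Character vector of length 8.
#' @export
feature_names <- function() FEATURE_NAMES

# Validate an 8-bit grayscale image matrix: integer-valued, in [0, 255].
assert_gray <- function(image, min_dim = 1L, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(image)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  if (min(image) < 0 || max(image) > 255) {
    stop(sprintf("`%s` intensities must lie in [0, 255]", arg), call. = FALSE)
  }
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    stop(sprintf("`%s` must be at least %d x %d", arg, min_dim, min_dim),
         call. = FALSE)
  }
  invisible(image)
}

# Clip to [0, 255] and round to integer grey levels.
clip_gray <- function(x) {
  storage.mode(x) <- "double"
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

# Derive a child seed from a parent seed and a stream offset, staying within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% .Machine$integer.max)
}

# Labels are 0 = normal, 1 = abnormal (positive class).
assert_labels <- function(y) {
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("labels must be 0 (normal) or 1 (abnormal)", call. = FALSE)
  }
  as.integer(y)
}

# Split a labeled data frame into the numeric feature matrix and label vector.
# `data` carries features in all columns except `label_col`.
split_xy <- function(data, label_col = "label") {
  if (!label_col %in% names(data)) {
    stop(sprintf("column `%s` not found in data", label_col), call. = FALSE)
  }
  y <- assert_labels(data[[label_col]])
  x_cols <- setdiff(names(data), label_col)
  keep <- x_cols[vapply(data[x_cols], is.numeric, logical(1))]
  if (length(keep) < 1L) stop("no numeric feature columns found", call. = FALSE)
  X <- as.matrix(data[keep])
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  list(X = X, y = y, feature_names = keep)
}

# Stratified fold assignment: within each class, shuffle (seeded) and deal
# round-robin so fold sizes differ by at most one per class.
stratified_folds <- function(y, folds, seed) {
  y <- assert_labels(y)
  for (cl in unique(y)) {
    if (sum(y == cl) < folds) {
      stop(sprintf("class %d has fewer members (%d) than folds (%d)",
                   cl, sum(y == cl), folds), call. = FALSE)
    }
  }
  fold_id <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}
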