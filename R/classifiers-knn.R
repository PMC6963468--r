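#' Fit a k-nearest-neighbour classifier
#'
#' Stores the training points together with per-feature min-max scaling
#' parameters learned from the training data, so Euclidean distances are
#' computed on features scaled to `[0, 1]` (unscaled distances would be
#' dominated by the feature with the largest spread, e.g. variance vs
#' entropy). The default `k = 2` follows the pipeline configuration.
#'
#' @param data Data frame with numeric feature columns and a binary label
#'   column (0 = normal, 1 = abnormal).
#' @param k Number of neighbours (default 2).
#' @param label_col Name of the label column (default `"label"`).
#' @return A fitted `knn_model`.
#' @export
knn_fit <- function(data, k = 2, label_col = "label") {
  d <- split_xy(data, label_col)
  k <- as.integer(k)
  if (k < 1 || k > nrow(d$X)) {
    stop(sprintf("k = %d must be in [1, n = %d]", k, nrow(d$X)), call. = FALSE)
  }
  mins <- apply(d$X, 2, min)
  ranges <- apply(d$X, 2, max) - mins
  ranges[ranges == 0] <- 1         # constant features map to 0
  structure(
    list(kind = "knn", k = k,
         X = scale(d$X, center = mins, scale = ranges),
         y = d$y, mins = mins, ranges = ranges,
         feature_names = d$feature_names, label_col = label_col),
    class = c("knn_model", "mc_model"))
}

#' @export
predict.knn_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Xq <- query_matrix(object, newdata)
  Xq <- scale(Xq, center = object$mins, scale = object$ranges)
  Xt <- object$X
  k <- object$k
  n <- nrow(Xt)
  res <- t(vapply(seq_len(nrow(Xq)), function(i) {
    dd <- sqrt(colSums((t(Xt) - Xq[i, ])^2))
    ord <- order(dd, seq_len(n))          # distance ties broken by train index
    nb <- ord[seq_len(k)]
    p1 <- mean(object$y[nb] == 1)
    # hard class: majority; on a tie the nearer neighbour decides, and an
    # exact distance tie between the classes falls to class 0
    if (p1 > 0.5) cls <- 1L
    else if (p1 < 0.5) cls <- 0L
    else {
      d0 <- suppressWarnings(min(dd[nb][object$y[nb] == 0]))
      d1 <- suppressWarnings(min(dd[nb][object$y[nb] == 1]))
      cls <- if (d1 < d0) 1L else 0L
    }
    c(1 - p1, p1, cls)
  }, numeric(3)))
  finish_prediction(res, type)
}

# Shared helpers for the classifier predict methods ---------------------------

query_matrix <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$feature_names, names(newdata))
  if (length(missing)) {
    stop(sprintf("query is missing feature columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.matrix(newdata[object$feature_names])
}

finish_prediction <- function(res, type) {
  prob <- tibble::tibble(p0 = res[, 1], p1 = res[, 2])
  if (type == "prob") prob else as.integer(res[, 3])
}

#' @export
print.mc_model <- function(x, ...) {
  cat(sprintf("<%s> fitted on %d features: %s\n", x$kind,
              length(x$feature_names), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}
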